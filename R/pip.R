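# Desk-scale pull-into-place (PIP) design loop: restrained backbone
# generation across segment-length variants, fragment-sequence adoption,
# multi-metric Pareto selection, unrestrained re-prediction and score-gap
# analysis. Sequence change comes solely from loophash fragment adoption
# (the deliberate simplification of the design step in this backbone-only
# model).

#' Define a PIP design task
#'
#' @param start The starting `backbone` structure.
#' @param segment The [segment_spec()] to reshape.
#' @param restraints A [restraint_set()] pulling functional atoms toward
#'   their desired positions.
#' @param length_deltas Segment length changes relative to native, each in
#'   `0 .. -6`; deleted residues are taken from the downstream end of the
#'   segment. Candidates are only ever compared within one delta.
#' @param keep_per_delta Candidates kept per delta by the restraint filter.
#' @param max_designs Maximum designs carried into re-prediction.
#' @return A `design_task` list.
#' @export
design_task <- function(start, segment, restraints, length_deltas = c(0L, -1L),
                        keep_per_delta = 10L, max_designs = 5L) {
  length_deltas <- as.integer(length_deltas)
  if (any(length_deltas > 0L | length_deltas < -6L)) {
    stop("length_deltas must lie in 0 .. -6", call. = FALSE)
  }
  L <- segment$end - segment$start + 1L
  if (any(L + length_deltas < 3L)) {
    stop("length_deltas would shrink the segment below 3 residues", call. = FALSE)
  }
  structure(list(start = start, segment = segment, restraints = restraints,
                 length_deltas = length_deltas,
                 keep_per_delta = as.integer(keep_per_delta),
                 max_designs = as.integer(max_designs)),
            class = "design_task")
}

# Segment-length variant: delete |delta| residues from the downstream end
# of the segment (retained residues keep their numbering; the numbering gap
# is bridged by closure during sampling). Restrained residues must survive.
shorten_segment <- function(bb, segment, delta, restraints = NULL) {
  if (delta == 0L) return(list(structure = bb, segment = segment))
  drop <- seq(segment$end + delta + 1L, segment$end)
  if (!is.null(restraints) &&
      any(restraints$chain == segment$chain & restraints$resnum %in% drop)) {
    stop("length delta ", delta, " would delete a restrained residue", call. = FALSE)
  }
  keep <- !(bb$chain == segment$chain & bb$resnum %in% drop)
  out <- as_backbone(bb[keep, , drop = FALSE], validate = FALSE)
  list(structure = out,
       segment = segment_spec(segment$chain, segment$start, segment$end + delta))
}

#' Generate restrained backbone candidates
#'
#' PIP step 1: runs the sampler with the restraint energy active, once per
#' length delta, pooling all models as design candidates tagged by delta
#' (candidates are never ranked across deltas).
#'
#' @param task A [design_task()].
#' @param config A [sampler_config()]; its restraints are replaced by the
#'   task's and its mode is typically `"lhkic"` (PIP v2) or `"kic"` (v1).
#' @param db Loophash database for lhkic mode.
#' @param library Fragment library for fkic/ccd modes.
#' @return A candidates tibble: candidate_id, delta, model metrics and the
#'   structure/segment in list-columns.
#' @export
generate_restrained_backbones <- function(task, config, db = NULL, library = NULL) {
  out <- list()
  for (delta in task$length_deltas) {
    var <- shorten_segment(task$start, task$segment, delta, task$restraints)
    cfg <- config
    cfg$restraints <- task$restraints
    cfg$seed <- config$seed + 10000L * abs(delta)
    start <- initialize_segment(var$structure, var$segment, cfg$init)
    ens <- run_monte_carlo(start, var$segment, cfg, db = db, library = library)
    mods <- ens$models[!ens$models$failed, , drop = FALSE]
    if (nrow(mods) == 0) next
    mods$delta <- delta
    mods$candidate_id <- sprintf("d%d_m%02d", delta, mods$model)
    mods$segment <- list(var$segment)
    out[[length(out) + 1L]] <- mods
  }
  if (!length(out)) stop("no restrained backbones were generated", call. = FALSE)
  dplyr::bind_rows(out)
}

#' Filter candidates by restraint satisfaction
#'
#' Keeps, within each length delta, the `keep_n` candidates whose restraint
#' satisfaction is smallest (stable order).
#'
#' @param candidates Candidates tibble with `restraint_satisfaction` and
#'   `delta` columns.
#' @param keep_n Candidates kept per delta (> 0).
#' @return The filtered tibble.
#' @export
filter_by_restraint_satisfaction <- function(candidates, keep_n) {
  if (keep_n <= 0) stop("keep_n must be > 0", call. = FALSE)
  keep <- logical(nrow(candidates))
  for (d in unique(candidates$delta)) {
    idx <- which(candidates$delta == d)
    best <- idx[order(candidates$restraint_satisfaction[idx])]
    keep[best[seq_len(min(keep_n, length(best)))]] <- TRUE
  }
  candidates[keep, , drop = FALSE]  # stable: input order preserved
}

#' Adopt fragment sequences on candidates
#'
#' PIP step 2 (simplified): each candidate's segment residues take the
#' amino acids of the loophash entry applied by its best accepted move
#' (recorded in the sampling lineage); candidates without such lineage are
#' returned unchanged. Deterministic given the lineage.
#'
#' @param candidates Candidates tibble from
#'   [generate_restrained_backbones()].
#' @param db Loophash database (unused when every candidate carries
#'   lineage; kept for interface compatibility).
#' @return The candidates with updated structures and a `sequence` column.
#' @export
adopt_fragment_sequences <- function(candidates, db = NULL) {
  candidates$sequence <- NA_character_
  for (i in seq_len(nrow(candidates))) {
    st <- candidates$structure[[i]]
    seg <- candidates$segment[[i]]
    info <- candidates$move_info[[i]]
    if (!is.null(info$entry)) {
      ri <- segment_res_idx(st, seg)
      st$aa[residue_rows(ri)] <- rep(info$entry$torsions$aa, each = 4L)
      candidates$structure[[i]] <- st
    }
    ri <- segment_res_idx(st, seg)
    candidates$sequence[i] <- paste(bb_residues(st)$aa[ri], collapse = "")
  }
  candidates
}

#' Exact Pareto front under minimisation
#'
#' Returns the non-dominated candidates for the named metrics (all
#' minimised): no member is dominated by any candidate, every non-member is
#' dominated by some member, and exact ties on all metrics are both kept.
#' Fronts larger than `max_out` are subsampled by NSGA-style crowding
#' distance (boundary points first).
#'
#' @param candidates Candidates tibble carrying the metric columns.
#' @param metric_names Character vector of metric column names.
#' @param max_out Maximum front size (default unlimited).
#' @return The front as a tibble subset of `candidates`.
#' @export
pareto_select <- function(candidates, metric_names, max_out = Inf) {
  miss <- setdiff(metric_names, names(candidates))
  if (length(miss)) stop("missing metric column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  M <- as.matrix(candidates[, metric_names, drop = FALSE])
  if (anyNA(M)) {
    bad <- which(rowSums(is.na(M)) > 0)[1]
    stop("candidate ", bad, " is missing metric values", call. = FALSE)
  }
  n <- nrow(M)
  dominated <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (dominated[i]) next
    le <- rowSums(M <= matrix(M[i, ], n, ncol(M), byrow = TRUE)) == ncol(M)
    lt <- rowSums(M < matrix(M[i, ], n, ncol(M), byrow = TRUE)) > 0
    if (any(le & lt & seq_len(n) != i)) dominated[i] <- TRUE
  }
  front <- which(!dominated)
  if (length(front) > max_out) {
    Fm <- M[front, , drop = FALSE]
    crowd <- rep(0, length(front))
    for (j in seq_len(ncol(Fm))) {
      ord <- order(Fm[, j])
      rng <- diff(range(Fm[, j]))
      crowd[ord[c(1, length(ord))]] <- Inf
      if (rng > 0 && length(ord) > 2) {
        for (k in 2:(length(ord) - 1)) {
          crowd[ord[k]] <- crowd[ord[k]] +
            (Fm[ord[k + 1], j] - Fm[ord[k - 1], j]) / rng
        }
      }
    }
    front <- front[order(-crowd)][seq_len(max_out)]
    front <- sort(front)
  }
  candidates[front, , drop = FALSE]
}

#' Boltzmann-weighted candidate selection
#'
#' Samples `n` candidates without replacement with probability proportional
#' to `exp(-total / temperature)`; as the temperature approaches zero the
#' minimum-energy candidate is always drawn first.
#'
#' @param candidates Candidates tibble with a `total` energy column.
#' @param temperature Selection temperature (> 0).
#' @param n Number of candidates to draw (at most the pool size).
#' @return The sampled rows, in draw order.
#' @export
boltzmann_select <- function(candidates, temperature, n) {
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (n > nrow(candidates)) stop("cannot draw more candidates than the pool holds",
                                 call. = FALSE)
  w <- exp(-(candidates$total - min(candidates$total)) / temperature)
  idx <- sample.int(nrow(candidates), n, replace = FALSE, prob = w)
  candidates[idx, , drop = FALSE]
}

#' Unrestrained re-prediction and score-gap analysis
#'
#' PIP step 3: for each design candidate, runs an unrestrained prediction
#' from an extended start of its (possibly mutated) structure, measures the
#' restraint satisfaction of every model (restraints are used only for
#' measurement), partitions models into satisfied (< 1 Angstrom) and
#' unsatisfied (> 2 Angstrom) classes - the 1-2 Angstrom band is excluded -
#' and reports the score gap `min(total | unsatisfied) - min(total |
#' satisfied)` (positive when every well-scoring model adopts the target
#' geometry). Candidates whose every model is satisfied have an undefined
#' gap and rank highest; candidates with no satisfied model are flagged
#' failures.
#'
#' @param candidates Candidates tibble (with structures and segments).
#' @param restraints The measurement [restraint_set()].
#' @param config A [sampler_config()] for the prediction runs (its
#'   restraints are removed).
#' @param sources Fragment sources for per-candidate FKIC libraries.
#' @param sizes Fragment sizes for the libraries.
#' @return A list: `report` (tibble: candidate_id, delta, n_satisfied,
#'   n_unsatisfied, gap, gap_defined, all_satisfied, no_satisfied,
#'   lowest_energy_satisfied, min_satisfaction; ranked by gap) and
#'   `ensembles` (per-candidate prediction ensembles with a
#'   `satisfaction` column added to each model row).
#' @export
predict_and_gap <- function(candidates, restraints, config, sources,
                            sizes = c(3L, 9L)) {
  cfg <- config
  cfg$restraints <- NULL
  rows <- list(); ensembles <- list()
  for (i in seq_len(nrow(candidates))) {
    st <- candidates$structure[[i]]
    seg <- candidates$segment[[i]]
    qy <- segment_query(st, seg, context = 3L)
    lib <- build_fragment_library(sources, qy$query, sizes = sizes,
                                  seg_offset = qy$seg_offset)
    start <- initialize_segment(st, seg, cfg$init)
    ens <- run_monte_carlo(start, seg, cfg, library = lib)
    mods <- ens$models[!ens$models$failed, , drop = FALSE]
    sat_d <- vapply(mods$structure, function(s) restraint_satisfaction(s, restraints),
                    numeric(1))
    ens$models$satisfaction <- NA_real_
    ens$models$satisfaction[!ens$models$failed] <- sat_d
    ensembles[[candidates$candidate_id[i]]] <- ens
    sat <- sat_d < 1
    unsat <- sat_d > 2
    gap <- if (any(sat) && any(unsat)) {
      min(mods$total[unsat]) - min(mods$total[sat])
    } else NA_real_
    rows[[i]] <- tibble::tibble(
      candidate_id = candidates$candidate_id[i], delta = candidates$delta[i],
      n_models = nrow(mods), n_satisfied = sum(sat), n_unsatisfied = sum(unsat),
      gap = gap, gap_defined = !is.na(gap),
      all_satisfied = all(sat), no_satisfied = !any(sat),
      lowest_energy_satisfied = sat[which.min(mods$total)],
      min_satisfaction = min(sat_d))
  }
  rep <- dplyr::bind_rows(rows)
  # all-satisfied candidates first, then by descending gap, failures last
  ord <- order(!rep$all_satisfied, -ifelse(is.na(rep$gap), -Inf, rep$gap),
               rep$no_satisfied)
  rep <- rep[ord, , drop = FALSE]
  rep$rank <- seq_len(nrow(rep))
  list(report = rep, ensembles = ensembles)
}

#' Run the full PIP pipeline on a task
#'
#' Composes restrained generation, the restraint-satisfaction filter,
#' fragment-sequence adoption, Pareto selection (total energy, restraint
#' satisfaction, clash, rama) and unrestrained re-prediction.
#'
#' @param task A [design_task()].
#' @param generate_config Sampler config for restrained generation
#'   (lhkic with mutation recommended).
#' @param predict_config Sampler config for re-prediction (fkic).
#' @param db Loophash database.
#' @param sources Fragment sources for re-prediction libraries.
#' @return A list: `candidates` (post-filter), `front`, `report` (gap
#'   analysis).
#' @export
run_pip <- function(task, generate_config, predict_config, db, sources) {
  cands <- generate_restrained_backbones(task, generate_config, db = db)
  cands <- filter_by_restraint_satisfaction(cands, task$keep_per_delta)
  cands <- adopt_fragment_sequences(cands, db)
  front <- pareto_select(cands, c("total", "restraint_satisfaction", "clash", "rama"),
                         max_out = task$max_designs)
  pg <- predict_and_gap(front, task$restraints, predict_config, sources)
  list(candidates = cands, front = front, report = pg$report,
       prediction_ensembles = pg$ensembles)
}
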