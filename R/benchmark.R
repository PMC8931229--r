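# Benchmark preparation and the two headline ensemble metrics: the RMSD of
# the lowest-energy model and the fraction of sub-angstrom models, with
# dataset medians and the fragment-distance correlation analysis.

#' Prepare a benchmark case for prediction
#'
#' Erases the native segment conformation from the start structure by
#' rebuilding each segment idealised-extended (phi/psi = 180); the native
#' conformation is retained only in the returned case record. Side-chain
#' stripping is vacuous in this backbone-only model and recorded as such.
#'
#' @param native The native `backbone` tibble.
#' @param segments A [segment_spec()] or list of them; segments must not
#'   touch chain termini (closure needs both anchors).
#' @return A list with `start` (the extended-start structure), `native`,
#'   `segments` and `sidechains_stripped = NA` (not applicable).
#' @export
prepare_case <- function(native, segments) {
  if (inherits(segments, "segment_spec")) segments <- list(segments)
  res <- bb_residues(native)
  start <- native
  for (seg in segments) {
    ri <- segment_res_idx(native, seg)
    if (ri[1] == 1L || ri[length(ri)] == nrow(res)) {
      stop("segment touches a chain terminus; closure needs both anchors",
           call. = FALSE)
    }
    start <- initialize_segment(start, seg, init = "extended")
  }
  list(start = start, native = native, segments = segments,
       sidechains_stripped = NA)
}

#' Ensemble metrics of a model set
#'
#' `lowest_energy_rmsd` is the segment RMSD of the single best-total-energy
#' model (ties broken by lower model index); `fraction_subangstrom` is the
#' proportion of models with RMSD < 1 Angstrom. Failed models are excluded
#' from both.
#'
#' @param models A `loop_ensemble` or its `models` tibble (columns `total`,
#'   `rmsd` and optionally `failed`).
#' @param case_id Optional case label.
#' @return A one-row tibble: case_id, n_models, lowest_energy_rmsd,
#'   fraction_subangstrom.
#' @export
evaluate_ensemble <- function(models, case_id = NA_character_) {
  if (inherits(models, "loop_ensemble")) models <- models$models
  if ("failed" %in% names(models)) models <- models[!models$failed, , drop = FALSE]
  if (nrow(models) == 0) stop("no successful models to evaluate", call. = FALSE)
  best <- which.min(models$total) # which.min takes the first of tied minima
  tibble::tibble(case_id = case_id, n_models = nrow(models),
                 lowest_energy_rmsd = models$rmsd[best],
                 fraction_subangstrom = mean(models$rmsd < 1))
}

#' Dataset summary of per-case metrics
#'
#' Medians across cases of the lowest-energy-model RMSD and of the
#' sub-angstrom fraction (R's default median: mean of the middle two for
#' even counts).
#'
#' @param metrics A tibble of per-case rows from [evaluate_ensemble()].
#' @return A one-row tibble: n_cases, median_lowest_energy_rmsd,
#'   median_fraction_subangstrom.
#' @export
dataset_summary <- function(metrics) {
  if (nrow(metrics) < 1) stop("need at least one case", call. = FALSE)
  tibble::tibble(
    n_cases = nrow(metrics),
    median_lowest_energy_rmsd = stats::median(metrics$lowest_energy_rmsd),
    median_fraction_subangstrom = stats::median(metrics$fraction_subangstrom))
}

#' Best achievable 3-mer fragment distance of a case
#'
#' For every 3-mer alignment frame of the segment, the minimum mean chord
#' distance between any library fragment in that frame and the native
#' torsions, averaged over frames. Low values mean the library contains
#' near-native local structure.
#'
#' @param library A `fragment_library` with 3-mers for the case's segment.
#' @param native The native `backbone`.
#' @param segment The case [segment_spec()].
#' @return Mean over frames of the per-frame minimum mean fragment
#'   distance.
#' @export
case_fragment_distance <- function(library, native, segment) {
  nat <- backbone_torsions(native, segment)
  off <- attr(library, "seg_offset") %||% 0L
  lib3 <- library[library$size == 3L, , drop = FALSE]
  if (nrow(lib3) == 0) stop("library has no 3-mers", call. = FALSE)
  # frames fully inside the segment, in segment coordinates
  frames <- unique(lib3$start)
  seg_pos <- frames + off
  keep <- seg_pos >= 1L & seg_pos + 2L <= nrow(nat)
  frames <- frames[keep]; seg_pos <- seg_pos[keep]
  if (!length(frames)) stop("no 3-mer frame lies fully inside the segment", call. = FALSE)
  per_frame <- vapply(seq_along(frames), function(k) {
    target <- nat[seg_pos[k]:(seg_pos[k] + 2L), c("phi", "psi")]
    sub <- lib3[lib3$start == frames[k], , drop = FALSE]
    min(vapply(unique(sub$frag), function(fr) {
      mean_fragment_distance(sub[sub$frag == fr, c("phi", "psi")], target)
    }, numeric(1)))
  }, numeric(1))
  mean(per_frame)
}

#' Correlation between fragment quality and sampling success
#'
#' Spearman rank correlation between the per-case best mean 3-mer fragment
#' distance to native and the per-case fraction of sub-angstrom models.
#' Libraries with near-native fragments should concentrate sampling on
#' native-like conformations, making the correlation negative.
#'
#' @param fragment_distances Numeric vector of per-case
#'   [case_fragment_distance()] values.
#' @param fractions Numeric vector of per-case sub-angstrom fractions.
#' @return A list with `rho` (Spearman correlation) and `defined`
#'   (`FALSE`, with `rho = NA`, when either variable is constant).
#' @export
fragment_distance_correlation <- function(fragment_distances, fractions) {
  if (length(fragment_distances) != length(fractions)) {
    stop("inputs must have equal length", call. = FALSE)
  }
  if (length(fractions) < 3) stop("need at least 3 cases", call. = FALSE)
  if (stats::sd(fragment_distances) == 0 || stats::sd(fractions) == 0) {
    return(list(rho = NA_real_, defined = FALSE))
  }
  rho <- suppressWarnings(
    stats::cor(fragment_distances, fractions, method = "spearman"))
  list(rho = rho, defined = TRUE)
}

#' Run a prediction benchmark over fixture cases
#'
#' For each case: prepares the extended start, builds (or receives) the
#' fragment inputs, runs the sampler and computes ensemble metrics.
#'
#' @param cases List of cases from [make_benchmark_set()].
#' @param config A [sampler_config()].
#' @param sources Named list of fragment source structures (fkic/ccd
#'   modes); ignored for other modes.
#' @param exclude_native Exclude `native_<case_id>` sources from each
#'   case's library (the homolog-exclusion regime).
#' @param db Loophash database (lhkic mode).
#' @param sizes Fragment sizes for library construction.
#' @return A list with `metrics` (per-case tibble incl. fragment
#'   distances), `summary` ([dataset_summary()]) and `ensembles`.
#' @export
run_benchmark <- function(cases, config, sources = NULL, exclude_native = TRUE,
                          db = NULL, sizes = c(3L, 9L)) {
  metrics <- list(); ensembles <- list()
  for (cs in cases) {
    prep <- prepare_case(cs$native, cs$segments)
    libs <- NULL
    if (config$mode %in% c("fkic", "ccd")) {
      libs <- lapply(prep$segments, function(seg) {
        qy <- segment_query(cs$native, seg, context = 3L)
        excl <- if (exclude_native) paste0("native_", cs$case_id) else character()
        build_fragment_library(sources, qy$query, sizes = sizes,
                               exclude_ids = excl, seg_offset = qy$seg_offset)
      })
    }
    ens <- run_monte_carlo(prep$start, prep$segments, config,
                           reference = cs$native, library = libs, db = db)
    em <- evaluate_ensemble(ens, cs$case_id)
    if (!is.null(libs)) {
      em$fragment_distance <- mean(vapply(seq_along(libs), function(k) {
        case_fragment_distance(libs[[k]], cs$native, prep$segments[[k]])
      }, numeric(1)))
    }
    metrics[[length(metrics) + 1L]] <- em
    ensembles[[cs$case_id]] <- ens
  }
  metrics <- dplyr::bind_rows(metrics)
  list(metrics = metrics, summary = dataset_summary(metrics),
       ensembles = ensembles)
}
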