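# Monte Carlo loop-modeling protocol. Each trajectory initialises the
# segment, then proposes closure moves (FKIC / LHKIC / Ramachandran-KIC /
# CCD) accepted by the Metropolis criterion on the simplified backbone
# energy under a geometric temperature anneal; the best-energy closed
# structure of each trajectory is recorded as one model.

#' Sampler configuration
#'
#' @param mode One of `"fkic"`, `"lhkic"`, `"kic"`, `"ccd"`.
#' @param n_models Number of independent trajectories (models).
#' @param outer_cycles,inner_cycles Cycle structure; the temperature anneals
#'   geometrically from `temp_start` to `temp_end` across outer cycles.
#' @param temp_start,temp_end Metropolis temperatures (> 0).
#' @param seed Master seed; trajectory i uses `seed + i`.
#' @param weights An [energy_weights()].
#' @param restraints Optional [restraint_set()] included in the energy.
#' @param mutate_on_lhkic Adopt loophash entry sequences during LHKIC moves.
#' @param init Segment initialisation: `"extended"` (phi/psi = 180) or
#'   `"random"` (Ramachandran draws).
#' @param rama_threshold Pivot Ramachandran screen floor (relative
#'   density; 0 disables the hard screen).
#' @param solution_pick How to choose among surviving closure solutions:
#'   `"random"` (uniform) or `"lowest-energy"` (score each closed
#'   candidate and take the best).
#' @param n_tau Closure solver scan resolution.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(mode = c("fkic", "lhkic", "kic", "ccd"),
                           n_models = 500, outer_cycles = 10, inner_cycles = 20,
                           temp_start = 2, temp_end = 0.6, seed = 1,
                           weights = energy_weights(), restraints = NULL,
                           mutate_on_lhkic = FALSE, init = c("extended", "random"),
                           rama_threshold = 1e-4,
                           solution_pick = c("random", "lowest-energy"),
                           n_tau = 360) {
  mode <- match.arg(mode)
  init <- match.arg(init)
  solution_pick <- match.arg(solution_pick)
  if (n_models < 1) stop("n_models must be >= 1", call. = FALSE)
  if (temp_start <= 0 || temp_end <= 0) stop("temperatures must be > 0", call. = FALSE)
  structure(list(mode = mode, n_models = as.integer(n_models),
                 outer_cycles = as.integer(outer_cycles),
                 inner_cycles = as.integer(inner_cycles),
                 temp_start = temp_start, temp_end = temp_end,
                 seed = as.integer(seed), weights = weights,
                 restraints = restraints, mutate_on_lhkic = mutate_on_lhkic,
                 init = init, rama_threshold = rama_threshold,
                 solution_pick = solution_pick,
                 n_tau = as.integer(n_tau)),
            class = "sampler_config")
}

#' Initialise a segment for sampling
#'
#' Rebuilds the segment with idealised geometry in an extended conformation
#' (all phi/psi = 180) or with torsions randomised from the Ramachandran
#' tables, erasing the native conformation. The downstream junction is left
#' broken until the first closure move.
#'
#' @param bb A `backbone` tibble.
#' @param segment A [segment_spec()].
#' @param init `"extended"` or `"random"`.
#' @param geometry An [ideal_geometry()].
#' @return The modified `backbone` tibble.
#' @export
initialize_segment <- function(bb, segment, init = "extended",
                               geometry = ideal_geometry()) {
  # capture the junction torsion phi(end+1) while the junction is intact;
  # it anchors the C-side of every subsequent closure (see torsions.R)
  jp <- attr(bb, "junction_phi")
  if (is.null(jp) || !junction_phi_key(segment) %in% names(jp)) {
    bb <- set_junction_phi(bb, segment, get_junction_phi(bb, segment))
  }
  resnums <- seq(segment$start, segment$end)
  if (init == "extended") {
    tor <- tibble::tibble(resnum = resnums, phi = 180, psi = 180, omega = 180)
  } else {
    res <- bb_residues(bb)
    ri <- segment_res_idx(bb, segment)
    cls <- rama_class(res$aa[ri],
                      ifelse(ri + 1 <= nrow(res), res$aa[pmin(ri + 1, nrow(res))], NA))
    draws <- purrr::map_dfr(cls, function(cl) sample_rama(1, cl))
    tor <- tibble::tibble(resnum = resnums, phi = draws$phi, psi = draws$psi,
                          omega = 180)
  }
  set_segment_torsions(bb, segment, tor, geometry)
}

# Shared closure tail of every KIC-family move: build the closure problem
# from a segment torsion table (pivot phi/psi free), solve, screen pivots,
# pick one surviving solution uniformly at random.
close_with_kic <- function(bb, segment, pivots, tor, config,
                           geometry = ideal_geometry()) {
  pr <- closure_problem(bb, segment, pivots, tor, geometry)
  sols <- solve_closure(pr, n_tau = config$n_tau)
  if (nrow(sols) == 0) return(NULL)
  res <- bb_residues(bb)
  ridx <- match(paste(segment$chain, pivots), paste(res$chain, res$resnum))
  nxt <- res$aa[pmin(ridx + 1L, nrow(res))]
  sols <- rama_filter(sols, res$aa[ridx], config$rama_threshold, nxt)
  if (nrow(sols) == 0) return(NULL)
  if ((config$solution_pick %||% "random") == "lowest-energy" && nrow(sols) > 1L) {
    totals <- vapply(seq_len(nrow(sols)), function(i) {
      score_backbone(apply_closure_solution(pr, sols[i, ]), config$weights,
                     config$restraints)$total
    }, numeric(1))
    pick <- which.min(totals)
  } else {
    pick <- if (nrow(sols) == 1L) 1L else sample(nrow(sols), 1L)
  }
  sol <- sols[pick, ]
  list(structure = apply_closure_solution(pr, sol),
       solution = sol, pivots = pivots, torsions = pr$torsions)
}

#' One FKIC move
#'
#' Picks a random fragment, applies its torsions to the overlapped
#' nonpivot positions, and closes the chain with KIC (random surviving
#' solution). When no closure solution survives, the move is rejected and
#' the structure returned unchanged.
#'
#' @param bb A `backbone` tibble.
#' @param segment A [segment_spec()].
#' @param library A [build_fragment_library()] result.
#' @param config A [sampler_config()].
#' @param geometry An [ideal_geometry()].
#' @return A list: `structure`, `closed` (logical), and move diagnostics.
#' @export
fkic_move <- function(bb, segment, library, config = sampler_config("fkic"),
                      geometry = ideal_geometry()) {
  fr <- pick_fragment(library)
  pivots <- select_pivots(segment)
  tor <- segment_torsion_state(bb, segment)
  off <- attr(library, "seg_offset") %||% 0L
  seg_pos <- fr$start + fr$torsions$pos - 1L + off
  keep <- seg_pos >= 1L & seg_pos <= nrow(tor)
  tor$phi[seg_pos[keep]] <- fr$torsions$phi[keep]
  tor$psi[seg_pos[keep]] <- fr$torsions$psi[keep]
  tor$omega[seg_pos[keep]] <- fr$torsions$omega[keep]
  closed <- close_with_kic(bb, segment, pivots, tor, config, geometry)
  if (is.null(closed)) {
    return(list(structure = bb, closed = FALSE, fragment = fr, pivots = pivots))
  }
  list(structure = closed$structure, closed = TRUE, fragment = fr,
       pivots = pivots, torsions = closed$torsions, solution = closed$solution)
}

#' One LHKIC move
#'
#' Computes the 6D transform between the residue before the first pivot and
#' the residue after the last pivot, queries the loophash database, applies
#' a random returned loop (optionally adopting its sequence) and closes
#' with KIC.
#'
#' @param bb A `backbone` tibble.
#' @param segment A [segment_spec()].
#' @param db A [build_loophash_db()] database covering the segment length.
#' @param config A [sampler_config()].
#' @param mutate Adopt the entry's amino acids (defaults to the config).
#' @param geometry An [ideal_geometry()].
#' @return A list as for [fkic_move()], with `entry` diagnostics.
#' @export
lhkic_move <- function(bb, segment, db, config = sampler_config("lhkic"),
                       mutate = config$mutate_on_lhkic,
                       geometry = ideal_geometry()) {
  pivots <- select_pivots(segment)
  L <- segment$end - segment$start + 1L
  if (!L %in% db$lengths) {
    # empty or mismatched database: the move is rejected, not an error
    return(list(structure = bb, closed = FALSE, entry = NULL, pivots = pivots))
  }
  tf <- segment_rigid_transform(bb, segment$start - 1L, segment$end + 1L,
                                chain = segment$chain)
  hits <- query_loophash(db, tf, L)
  if (!length(hits)) {
    return(list(structure = bb, closed = FALSE, entry = NULL, pivots = pivots))
  }
  entry <- hits[[if (length(hits) == 1L) 1L else sample(length(hits), 1L)]]
  tor <- tibble::tibble(resnum = seq(segment$start, segment$end),
                        phi = entry$torsions$phi, psi = entry$torsions$psi,
                        omega = entry$torsions$omega)
  closed <- close_with_kic(bb, segment, pivots, tor, config, geometry)
  if (is.null(closed)) {
    return(list(structure = bb, closed = FALSE, entry = entry, pivots = pivots))
  }
  out <- closed$structure
  if (mutate) {
    ri <- segment_res_idx(out, segment)
    out$aa[residue_rows(ri)] <- rep(entry$torsions$aa, each = 4L)
  }
  list(structure = out, closed = TRUE, entry = entry, pivots = pivots,
       torsions = closed$torsions, solution = closed$solution)
}

# Ramachandran-KIC baseline move: nonpivot torsions drawn independently
# from the residue-class Ramachandran tables (omega trans).
rama_kic_move <- function(bb, segment, config = sampler_config("kic"),
                          geometry = ideal_geometry()) {
  pivots <- select_pivots(segment)
  res <- bb_residues(bb)
  ri <- segment_res_idx(bb, segment)
  cls <- rama_class(res$aa[ri], res$aa[pmin(ri + 1L, nrow(res))])
  draws <- purrr::map_dfr(cls, function(cl) sample_rama(1, cl))
  tor <- tibble::tibble(resnum = seq(segment$start, segment$end),
                        phi = draws$phi, psi = draws$psi, omega = 180)
  closed <- close_with_kic(bb, segment, pivots, tor, config, geometry)
  if (is.null(closed)) {
    return(list(structure = bb, closed = FALSE, pivots = pivots))
  }
  list(structure = closed$structure, closed = TRUE, pivots = pivots,
       torsions = closed$torsions, solution = closed$solution)
}

# CCD baseline move: fragment insertion then cyclic coordinate descent.
ccd_move <- function(bb, segment, library, config = sampler_config("ccd"),
                     geometry = ideal_geometry()) {
  fr <- pick_fragment(library)
  off <- attr(library, "seg_offset") %||% 0L
  broken <- insert_fragment_torsions(bb, segment, fr$start + off, fr$torsions,
                                     geometry)
  closed <- ccd_close(broken, segment, max_iters = 30, tol = 0.05, geometry = geometry)
  if (closed$break_distance > 0.05) {
    return(list(structure = bb, closed = FALSE, fragment = fr))
  }
  list(structure = closed$structure, closed = TRUE, fragment = fr)
}

metropolis_accept <- function(delta_e, temperature) {
  delta_e <= 0 || stats::runif(1) < exp(-delta_e / temperature)
}

#' Run the Monte Carlo loop-modeling protocol
#'
#' Generates `config$n_models` independent trajectories. Each trajectory
#' initialises the segment(s), then performs `outer_cycles x inner_cycles`
#' moves with Metropolis acceptance at a geometrically annealed
#' temperature, tracking the best-energy closed structure. Move failures
#' (no closure solution, empty loophash query) count as rejected steps.
#'
#' @param bb The starting `backbone` tibble.
#' @param segments A [segment_spec()] or list of them (a random segment is
#'   remodeled at each move).
#' @param config A [sampler_config()].
#' @param reference Optional native `backbone` for RMSD bookkeeping.
#' @param library A fragment library (fkic/ccd modes), or a list of one
#'   library per segment.
#' @param db A loophash database (lhkic mode).
#' @param geometry An [ideal_geometry()].
#' @return A `loop_ensemble`: list with `models` (one row per model:
#'   energies, segment RMSD, restraint satisfaction, closure residual,
#'   acceptance counts, and the structure in a list-column), plus the
#'   config, segments and reference.
#' @export
run_monte_carlo <- function(bb, segments, config, reference = NULL,
                            library = NULL, db = NULL,
                            geometry = ideal_geometry()) {
  if (inherits(segments, "segment_spec")) segments <- list(segments)
  if (inherits(library, "fragment_library")) {
    library <- rep(list(library), length(segments))
  }
  if (config$mode %in% c("fkic", "ccd") && is.null(library)) {
    stop("mode ", config$mode, " requires a fragment library", call. = FALSE)
  }
  if (config$mode == "lhkic" && is.null(db)) {
    stop("lhkic mode requires a loophash database", call. = FALSE)
  }
  temps <- config$temp_start *
    (config$temp_end / config$temp_start)^(seq_len(config$outer_cycles) - 1)
  if (config$outer_cycles == 1) temps <- config$temp_start

  records <- vector("list", config$n_models)
  for (i in seq_len(config$n_models)) {
    set.seed(config$seed + i)
    cur <- bb
    for (seg in segments) cur <- initialize_segment(cur, seg, config$init, geometry)
    cur_score <- score_backbone(cur, config$weights, config$restraints)
    best <- NULL; best_score <- NULL; best_info <- NULL
    best_trace <- double()
    accepted <- 0L; attempted <- 0L; failures <- 0L
    err <- NULL
    tryCatch({
      for (oc in seq_len(config$outer_cycles)) {
        temp <- temps[oc]
        for (ic in seq_len(config$inner_cycles)) {
          attempted <- attempted + 1L
          si <- if (length(segments) == 1L) 1L else sample(length(segments), 1L)
          seg <- segments[[si]]
          mv <- switch(config$mode,
            fkic = fkic_move(cur, seg, library[[si]], config, geometry),
            lhkic = lhkic_move(cur, seg, db, config, geometry = geometry),
            kic = rama_kic_move(cur, seg, config, geometry),
            ccd = ccd_move(cur, seg, library[[si]], config, geometry))
          if (!mv$closed) {
            failures <- failures + 1L
            next
          }
          new_score <- score_backbone(mv$structure, config$weights, config$restraints)
          if (metropolis_accept(new_score$total - cur_score$total, temp)) {
            cur <- mv$structure
            cur_score <- new_score
            accepted <- accepted + 1L
            if (is.null(best_score) || cur_score$total < best_score$total) {
              best <- cur; best_score <- cur_score
              best_info <- mv[setdiff(names(mv), "structure")]
            }
            best_trace <- c(best_trace, best_score$total)
          }
        }
      }
    }, error = function(e) err <<- conditionMessage(e))

    if (is.null(best)) {
      records[[i]] <- tibble::tibble(
        model = i, failed = TRUE, error = err %||% "no closed structure sampled",
        rama = NA_real_, clash = NA_real_, restraint = NA_real_, total = NA_real_,
        rmsd = NA_real_, restraint_satisfaction = NA_real_,
        closure_residual = NA_real_, accepted = accepted, attempted = attempted,
        move_failures = failures, seed = config$seed + i,
        structure = list(NULL), move_info = list(NULL),
        best_trace = list(best_trace))
    } else {
      resids <- vapply(segments, function(sg) closure_residual(best, sg, geometry),
                       numeric(1))
      rmsd <- if (is.null(reference)) NA_real_ else
        backbone_rmsd(best, reference, segments)
      records[[i]] <- tibble::tibble(
        model = i, failed = FALSE, error = NA_character_,
        rama = best_score$rama, clash = best_score$clash,
        restraint = best_score$restraint, total = best_score$total,
        rmsd = rmsd,
        restraint_satisfaction = restraint_satisfaction(best, config$restraints),
        closure_residual = max(resids), accepted = accepted,
        attempted = attempted, move_failures = failures,
        seed = config$seed + i,
        structure = list(best), move_info = list(best_info),
        best_trace = list(best_trace))
    }
  }
  structure(list(models = dplyr::bind_rows(records), config = config,
                 segments = segments, reference = reference),
            class = "loop_ensemble")
}

#' @export
print.loop_ensemble <- function(x, ...) {
  ok <- !x$models$failed
  cat(sprintf("<loop_ensemble: %d models (%s mode), %d failed>\n",
              nrow(x$models), x$config$mode, sum(!ok)))
  if (any(ok)) {
    cat(sprintf("  best total energy: %.3f", min(x$models$total[ok])))
    if (!all(is.na(x$models$rmsd[ok]))) {
      cat(sprintf(" | lowest-energy model RMSD: %.3f A",
                  x$models$rmsd[ok][which.min(x$models$total[ok])]))
    }
    cat("\n")
  }
  invisible(x)
}
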