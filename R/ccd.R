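# Cyclic coordinate descent closure - the classical fragment-insertion
# closure baseline. Unlike KIC, which changes only the three pivot
# phi/psi pairs analytically, CCD perturbs every torsion along the segment
# while iteratively shrinking the chain break.

#' Close a segment chain break by cyclic coordinate descent
#'
#' Sweeps over all segment phi/psi torsions; each torsion in turn is
#' adjusted by the closed-form rotation that minimises the distance of the
#' segment's virtual continuation (N, CA, C of the residue after the
#' segment) to its fixed target position. Omegas are kept fixed. The break
#' distance is non-increasing across iterations.
#'
#' @param bb A `backbone` tibble with a (possibly broken) downstream
#'   junction at the segment end.
#' @param segment A [segment_spec()].
#' @param max_iters Maximum number of full sweeps.
#' @param tol Break-distance convergence threshold in Angstrom.
#' @param geometry An [ideal_geometry()].
#' @return A list with elements `structure` (the adjusted `backbone`),
#'   `break_distance` (final RMS mismatch of the three junction atoms, in
#'   Angstrom), `iterations` (sweeps performed) and `trace` (break distance
#'   after each sweep).
#' @export
ccd_close <- function(bb, segment, max_iters = 100, tol = 0.1,
                      geometry = ideal_geometry()) {
  ri <- segment_res_idx(bb, segment)
  res <- bb_residues(bb)
  e <- ri[length(ri)]
  if (e + 1L > nrow(res) || res$chain[e + 1L] != res$chain[e]) {
    stop("segment has no downstream anchor residue", call. = FALSE)
  }
  tor <- segment_torsion_state(bb, segment)
  phi <- tor$phi; psi <- tor$psi; omega <- tor$omega
  L <- length(phi)
  target <- rbind(bb_xyz(bb, e + 1L, "N"), bb_xyz(bb, e + 1L, "CA"),
                  bb_xyz(bb, e + 1L, "C"))
  phi_next <- get_junction_phi(bb, segment)
  break_dist <- function(phi, psi, omega) {
    built <- rebuild_segment_coords(bb, ri, phi, psi, omega, geometry, phi_next)
    sqrt(mean(rowSums((built$next_ncac - target)^2)))
  }
  d0 <- break_dist(phi, psi, omega)
  trace <- double()
  iters <- 0L
  if (d0 > tol) {
    for (sweep in seq_len(max_iters)) {
      for (j in seq_len(L)) {
        for (which_t in c("phi", "psi")) {
          cur <- if (which_t == "phi") phi[j] else psi[j]
          built <- rebuild_segment_coords(bb, ri, phi, psi, omega, geometry, phi_next)
          co <- built$coords
          # rotation axis of this torsion in current coordinates
          if (which_t == "phi") {
            o1 <- co[(j - 1) * 4 + 1, ]; o2 <- co[(j - 1) * 4 + 2, ] # N -> CA
          } else {
            o1 <- co[(j - 1) * 4 + 2, ]; o2 <- co[(j - 1) * 4 + 3, ] # CA -> C
          }
          u <- vunit(o2 - o1)
          M <- built$next_ncac
          num <- 0; den <- 0
          for (k in 1:3) {
            foot <- o1 + sum((M[k, ] - o1) * u) * u
            rv <- M[k, ] - foot; sv <- target[k, ] - foot
            num <- num + sum(vcross(u, rv) * sv)
            den <- den + sum(rv * sv)
          }
          theta <- atan2(num, den) / DEG
          best <- cur; bestd <- break_dist(phi, psi, omega)
          for (cand in wrap_angle(c(cur + theta, cur - theta))) {
            if (which_t == "phi") phi[j] <- cand else psi[j] <- cand
            dd <- break_dist(phi, psi, omega)
            if (dd < bestd) { bestd <- dd; best <- cand }
          }
          if (which_t == "phi") phi[j] <- best else psi[j] <- best
        }
      }
      iters <- sweep
      trace <- c(trace, break_dist(phi, psi, omega))
      if (trace[length(trace)] < tol) break
    }
  }
  newtor <- tibble::tibble(resnum = tor$resnum, phi = phi, psi = psi, omega = omega)
  out <- set_segment_torsions(bb, segment, newtor, geometry)
  list(structure = out, break_distance = break_dist(phi, psi, omega),
       iterations = iters, trace = trace)
}
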