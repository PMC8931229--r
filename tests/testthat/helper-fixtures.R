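# Shared test fixtures, all generated in code. Expensive objects are built
# once per test run and cached in this environment.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# An irregular ideal-geometry chain with torsions drawn from broad ranges.
random_chain <- function(n, seed = 1) {
  set.seed(seed)
  backbone_from_torsions(tibble::tibble(
    phi = runif(n, -170, -40), psi = runif(n, -70, 170), omega = 180))
}

# An ideal alpha-helix.
helix_chain <- function(n = 10) {
  backbone_from_torsions(tibble::tibble(
    phi = rep(-57, n), psi = rep(-47, n), omega = 180))
}

# The standard 6-residue loop fixture with its native, sources (3 decoys +
# the native under a distinct id), query with context and libraries.
loop6 <- function() {
  cached("loop6", {
    fx <- make_fixture(fixture_spec(loop_length = 6, seed = 3))
    sources <- make_fragment_sources(3, seed = 9,
                                     natives = list(fix1 = fx$structure))
    qy <- segment_query(fx$structure, fx$segment, context = 3)
    list(
      native = fx$structure, segment = fx$segment, sources = sources,
      query = qy$query, offset = qy$seg_offset,
      lib_all = build_fragment_library(sources, qy$query, sizes = c(3, 9),
                                       seg_offset = qy$seg_offset),
      lib_native = build_fragment_library(sources["native_fix1"], qy$query,
                                          sizes = c(3, 9),
                                          seg_offset = qy$seg_offset),
      prep = prepare_case(fx$structure, fx$segment))
  })
}

# Random closure problem on a fresh irregular chain: 6-residue segment,
# random middle pivot, torsions measured from the native (so solutions are
# guaranteed non-empty, containing the native).
random_closure_problem <- function(seed) {
  bb <- random_chain(14, seed = seed)
  seg <- segment_spec("A", 5, 10)
  set.seed(seed + 5000)
  closure_problem(bb, seg, pivots = c(5L, sample(6:9, 1), 10L))
}

# Independent multistart oracle: enumerate the zeros of the closure
# residual over the six pivot torsions by Levenberg-Marquardt least squares
# from many random starts, using its own minimal forward-kinematics chain
# builder (no use of the package's closure machinery). Returns a list of
# torsion vectors (phi1, psi1, phi2, psi2, phi3, psi3) whose residual is
# below `tol` Angstrom.
multistart_oracle <- function(problem, n_starts = 250, tol = 1e-4, seed = 1) {
  pr <- problem
  ri <- loopforge:::segment_res_idx(pr$bb, pr$segment)
  rie <- ri[length(ri)]
  target <- rbind(loopforge:::bb_xyz(pr$bb, rie + 1L, "N"),
                  loopforge:::bb_xyz(pr$bb, rie + 1L, "CA"),
                  loopforge:::bb_xyz(pr$bb, rie + 1L, "C"))
  phi_next <- loopforge:::get_junction_phi(pr$bb, pr$segment)
  g <- pr$geometry
  s <- ri[1]
  aN <- loopforge:::bb_xyz(pr$bb, s - 1L, "N")
  aCA <- loopforge:::bb_xyz(pr$bb, s - 1L, "CA")
  aC <- loopforge:::bb_xyz(pr$bb, s - 1L, "C")
  psi0 <- dihedral_angle(aN, aCA, aC, loopforge:::bb_xyz(pr$bb, s, "N"))
  omega0 <- dihedral_angle(aCA, aC, loopforge:::bb_xyz(pr$bb, s, "N"),
                           loopforge:::bb_xyz(pr$bb, s, "CA"))
  L <- nrow(pr$torsions)
  # internal-coordinate template along the mainchain N-CA-C ... of the
  # segment plus the virtual continuation; unknown slots hold the pivots
  bonds <- rep(c(g$c_n, g$n_ca, g$ca_c), L + 1)
  angs <- rep(c(g$ca_c_n, g$c_n_ca, g$n_ca_c), L + 1)
  tors <- double(3 * (L + 1))
  tor <- pr$torsions
  tors[seq(1, by = 3, length.out = L + 1)] <- c(psi0, tor$psi)      # psi(i-1)
  tors[seq(2, by = 3, length.out = L + 1)] <- c(omega0, tor$omega)  # omega(i-1)
  tors[seq(3, by = 3, length.out = L)] <- tor$phi                   # phi(i)
  tors[3 * (L + 1)] <- phi_next
  pvpos <- match(pr$pivots, tor$resnum)
  phi_slot <- 3 * (pvpos - 1) + 3
  psi_slot <- 3 * pvpos + 1
  deg <- pi / 180
  fres <- function(x) {
    tt <- tors
    tt[phi_slot] <- x[c(1, 3, 5)]
    tt[psi_slot] <- x[c(2, 4, 6)]
    a <- aN; b <- aCA; cc <- aC
    n_at <- length(tt)
    last3 <- matrix(0, 3, 3)
    for (i in seq_len(n_at)) {
      bcv <- cc - b
      bc <- bcv / sqrt(sum(bcv * bcv))
      nv <- c((b - a)[2] * bc[3] - (b - a)[3] * bc[2],
              (b - a)[3] * bc[1] - (b - a)[1] * bc[3],
              (b - a)[1] * bc[2] - (b - a)[2] * bc[1])
      nv <- nv / sqrt(sum(nv * nv))
      mv <- c(nv[2] * bc[3] - nv[3] * bc[2], nv[3] * bc[1] - nv[1] * bc[3],
              nv[1] * bc[2] - nv[2] * bc[1])
      ang <- angs[i] * deg; torr <- tt[i] * deg
      d <- cc - bonds[i] * cos(ang) * bc +
        bonds[i] * sin(ang) * (cos(torr) * mv + sin(torr) * nv)
      a <- b; b <- cc; cc <- d
      if (i > n_at - 3) last3[i - (n_at - 3), ] <- d
    }
    as.numeric(last3 - target)
  }
  set.seed(seed)
  starts <- matrix(runif(6 * n_starts, -180, 180), ncol = 6)
  minima <- list()
  for (k in seq_len(n_starts)) {
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(starts[k, ], fn = fres,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 100, ftol = 1e-15, ptol = 1e-15))),
      error = function(e) NULL)
    if (is.null(fit)) next
    resid <- max(sqrt(rowSums(matrix(fres(fit$par), 3, 3)^2)))
    if (resid < tol) {
      x <- wrap_angle(fit$par)
      dup <- any(vapply(minima, function(m)
        max(abs(wrap_angle(m - x))) < 1, logical(1)))
      if (!dup) minima[[length(minima) + 1L]] <- x
    }
  }
  minima
}
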