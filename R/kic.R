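# Analytic kinematic closure (KIC). A closure problem fixes the anchors
# flanking a segment, the torsions of all nonpivot residues, and asks for
# every set of pivot phi/psi torsions that reconnects the chain.
#
# Geometry: with the three pivot CA atoms as vertices, the chain pieces
# between pivots are rigid bodies once nonpivot torsions are fixed, so the
# pivot-CA "virtual bond" lengths are constants. The middle pivot CA
# therefore lies on the circle cut by two spheres around the fixed end
# pivots; each connecting piece retains one spin angle about its virtual
# bond. The N-CA-C bond angle constraint at the two end pivots eliminates
# both spins in closed form (two branches each), leaving a single smooth
# residual in the circle angle tau whose roots - found by a dense scan plus
# bisection polish - enumerate all closure solutions (up to 16).

#' Select pivot residues for a KIC move
#'
#' The first and last segment residues are always pivots (the fixed anchors
#' bound the closure problem); the middle pivot is drawn uniformly at random
#' among interior residues. With `strategy = "all-random"` all three pivots
#' are redrawn uniformly, constrained to include both segment ends.
#'
#' @param segment A [segment_spec()] of length >= 3.
#' @param strategy Pivot scheme (see above).
#' @return Sorted integer vector of 3 pivot residue numbers.
#' @export
select_pivots <- function(segment, strategy = c("ends-random-middle", "all-random")) {
  strategy <- match.arg(strategy)
  s <- segment$start; e <- segment$end
  if (e - s + 1L < 3L) stop("segment must span at least 3 residues", call. = FALSE)
  if (e - s + 1L == 3L) return(c(s, s + 1L, e))
  interior <- seq(s + 1L, e - 1L)
  mid <- if (length(interior) == 1L) interior else sample(interior, 1L)
  # both strategies currently fix the end pivots; "all-random" redraws the
  # middle pivot too, which is the same draw - kept as an explicit option
  c(s, mid, e)
}

#' Construct a closure problem
#'
#' @param bb A `backbone` tibble.
#' @param segment A [segment_spec()]; the residues immediately before and
#'   after the segment must exist on the same chain (they are the fixed
#'   anchors).
#' @param pivots Integer vector of 3 strictly increasing pivot residue
#'   numbers inside the segment (defaults to [select_pivots()]).
#' @param torsions Data frame with columns resnum, phi, psi, omega giving
#'   the segment torsions; pivot phi/psi entries are ignored (they are the
#'   unknowns) while omega is honoured everywhere. Defaults to the torsions
#'   measured from `bb`.
#' @param geometry An [ideal_geometry()].
#' @return An object of class `closure_problem`.
#' @export
closure_problem <- function(bb, segment, pivots = select_pivots(segment),
                            torsions = NULL, geometry = ideal_geometry()) {
  ri <- segment_res_idx(bb, segment)
  res <- bb_residues(bb)
  if (ri[1] == 1L || ri[length(ri)] == nrow(res) ||
      res$chain[ri[1] - 1L] != segment$chain ||
      res$chain[ri[length(ri)] + 1L] != segment$chain) {
    stop("closure requires anchor residues on both sides of the segment", call. = FALSE)
  }
  pivots <- as.integer(pivots)
  if (length(pivots) != 3L || any(diff(pivots) <= 0L) ||
      pivots[1] < segment$start || pivots[3] > segment$end) {
    stop("pivots must be 3 strictly increasing residues inside the segment", call. = FALSE)
  }
  if (is.null(torsions)) torsions <- segment_torsion_state(bb, segment)
  j <- match(seq(segment$start, segment$end), torsions$resnum)
  if (anyNA(j)) stop("torsions must cover every segment residue", call. = FALSE)
  torsions <- torsions[j, , drop = FALSE]
  nonpivot <- !(torsions$resnum %in% pivots)
  need <- c(torsions$phi[nonpivot], torsions$psi[nonpivot], torsions$omega)
  if (anyNA(need) || !all(is.finite(need))) {
    stop("nonpivot torsions (and all omegas) must be fully specified and finite",
         call. = FALSE)
  }
  structure(list(bb = bb, segment = segment, pivots = pivots,
                 torsions = torsions, geometry = geometry),
            class = "closure_problem")
}

#' @export
print.closure_problem <- function(x, ...) {
  cat(sprintf("<closure_problem %s:%d-%d pivots %s>\n", x$segment$chain,
              x$segment$start, x$segment$end, paste(x$pivots, collapse = "/")))
  invisible(x)
}

# --- internals -------------------------------------------------------------

# Reference geometry of the rigid piece between two pivots a < b.
# Returns atoms [CA(a), C(a), N(a+1), CA(a+1), ..., N(b), CA(b)] built in an
# arbitrary frame from the fixed torsions: omega(a), then (phi, psi, omega)
# of each residue strictly between a and b.
leg_reference <- function(tor_seq, geometry) {
  g <- geometry
  n_extra <- length(tor_seq)
  a <- c(1, 1, 0); b <- c(1, 0, 0); ca0 <- c(0, 0, 0)
  c0 <- place_atom(a, b, ca0, g$ca_c, g$n_ca_c, 0)
  n1 <- place_atom(b, ca0, c0, g$c_n, g$ca_c_n, 0)
  atoms <- matrix(NA_real_, 3 + n_extra, 3)
  atoms[1, ] <- ca0; atoms[2, ] <- c0; atoms[3, ] <- n1
  # kinds cycle CA, C, N starting at the first extra atom
  bonds <- c(g$n_ca, g$ca_c, g$c_n)
  angs <- c(g$c_n_ca, g$n_ca_c, g$ca_c_n)
  p <- ca0; q <- c0; r <- n1
  for (i in seq_len(n_extra)) {
    k <- ((i - 1L) %% 3L) + 1L
    d <- place_atom(p, q, r, bonds[k], angs[k], tor_seq[i])
    atoms[3 + i, ] <- d
    p <- q; q <- r; r <- d
  }
  atoms
}

# Torsion sequence for the leg between pivots a and b from the problem's
# per-residue torsion table (rows indexed by position within the segment).
leg_torsion_seq <- function(tor, a_pos, b_pos) {
  seq_t <- tor$omega[a_pos]
  if (b_pos - a_pos > 1) {
    for (j in seq(a_pos + 1, b_pos - 1)) {
      seq_t <- c(seq_t, tor$phi[j], tor$psi[j], tor$omega[j])
    }
  }
  seq_t
}

# Backward chain building from the downstream anchor: seeds are C, CA, N of
# the residue after the last placed one; `tor_seq` is phi(e+1), omega(e),
# psi(e), phi(e), ... as needed. Atom kinds placed cycle C, CA, N.
build_backward <- function(seed_c, seed_ca, seed_n, tor_seq, geometry) {
  g <- geometry
  bonds <- c(g$c_n, g$ca_c, g$n_ca)
  angs <- c(g$c_n_ca, g$ca_c_n, g$n_ca_c)
  out <- matrix(NA_real_, length(tor_seq), 3)
  p <- seed_c; q <- seed_ca; r <- seed_n
  for (i in seq_along(tor_seq)) {
    k <- ((i - 1L) %% 3L) + 1L
    d <- place_atom(p, q, r, bonds[k], angs[k], tor_seq[i])
    out[i, ] <- d
    p <- q; q <- r; r <- d
  }
  out
}

clamp1 <- function(x) pmax(-1, pmin(1, x))

# Rodrigues rotation taking unit vector `a` onto each row of unit matrix B,
# applied to fixed point p (length 3). Returns n x 3.
rot_between_apply <- function(a, B, p) {
  vv <- mcross(matrix(a, nrow(B), 3, byrow = TRUE), B)
  cth <- as.numeric(B %*% a)
  pm <- matrix(p, nrow(B), 3, byrow = TRUE)
  pm * cth + mcross(vv, pm) + vv * (as.numeric(vv %*% p) / (1 + cth))
}

# Solve A cos(s) + B sin(s) = C for the two branches; returns list of two
# sigma vectors (NA where no real solution) and validity mask.
solve_phase <- function(A, B, C) {
  r <- sqrt(A^2 + B^2)
  ok <- r >= abs(C) & r > 0
  alpha <- atan2(B, A)
  beta <- acos(clamp1(C / r))
  list(plus = ifelse(ok, alpha + beta, NA_real_),
       minus = ifelse(ok, alpha - beta, NA_real_),
       ok = ok)
}

#' Solve a closure problem
#'
#' Enumerates all pivot phi/psi torsion sets that close the chain, by the
#' triangle reduction described in the package vignette. Every returned
#' solution, rebuilt forward through the segment, reconnects to the
#' downstream anchor within `tol` Angstrom, with nonpivot torsions exactly
#' as supplied. Returns zero rows when the anchors are out of reach.
#'
#' @param problem A [closure_problem()].
#' @param n_tau Number of scan points on the middle-pivot circle.
#' @param tol Closure residual tolerance in Angstrom.
#' @return A tibble with one row per solution: `tau`, `branch`, pivot
#'   torsions `phi1, psi1, phi2, psi2, phi3, psi3` (degrees) and
#'   `closure_residual` (Angstrom). The input problem is attached as
#'   attribute `problem`.
#' @export
solve_closure <- function(problem, n_tau = 360, tol = 1e-4) {
  pr <- problem
  g <- pr$geometry
  seg <- pr$segment
  tor <- pr$torsions
  ri <- segment_res_idx(pr$bb, seg)
  res <- bb_residues(pr$bb)
  s <- seg$start; e <- seg$end
  p1 <- pr$pivots[1]; p2 <- pr$pivots[2]; p3 <- pr$pivots[3]
  pos <- function(r) r - s + 1L
  empty <- tibble::tibble(tau = double(), branch = integer(),
                          phi1 = double(), psi1 = double(), phi2 = double(),
                          psi2 = double(), phi3 = double(), psi3 = double(),
                          closure_residual = double())

  # ---- fixed N-side. When the first pivot is the segment start (the
  # common case) the anchor frame comes straight from the structure; with a
  # prefix, it is rebuilt forward with the given nonpivot torsions.
  if (p1 == s) {
    N1 <- bb_xyz(pr$bb, ri[1], "N"); CA1 <- bb_xyz(pr$bb, ri[1], "CA")
    C_pre <- bb_xyz(pr$bb, ri[1] - 1L, "C")
  } else {
    tor_fill <- tor
    cur <- segment_torsion_state(pr$bb, seg)
    for (col in c("phi", "psi")) {
      piv <- tor_fill$resnum %in% pr$pivots
      tor_fill[[col]][piv & is.na(tor_fill[[col]])] <- cur[[col]][piv & is.na(tor_fill[[col]])]
    }
    bbw <- set_segment_torsions(pr$bb, seg, tor_fill, g)
    ri1 <- ri[pos(p1)]
    N1 <- bb_xyz(bbw, ri1, "N"); CA1 <- bb_xyz(bbw, ri1, "CA")
    C_pre <- bb_xyz(bbw, ri1 - 1L, "C")
  }

  # ---- fixed C-side: backward build from the downstream anchor
  rie <- ri[length(ri)]
  phi_next <- get_junction_phi(pr$bb, seg)
  back_seq <- phi_next
  if (p3 < e) {
    for (j in rev(seq(p3 + 1, e))) {
      back_seq <- c(back_seq, tor$omega[pos(j)], tor$psi[pos(j)], tor$phi[pos(j)])
    }
  }
  back_seq <- c(back_seq, tor$omega[pos(p3)])
  back <- build_backward(bb_xyz(pr$bb, rie + 1L, "C"), bb_xyz(pr$bb, rie + 1L, "CA"),
                         bb_xyz(pr$bb, rie + 1L, "N"), back_seq, g)
  nb <- nrow(back)
  CA3 <- back[nb, ]; C3 <- back[nb - 1L, ]
  N_after <- if (p3 == e) bb_xyz(pr$bb, rie + 1L, "N") else back[nb - 2L, ]

  # ---- rigid legs and the middle-pivot circle
  leg1 <- leg_reference(leg_torsion_seq(tor, pos(p1), pos(p2)), g)
  leg2 <- leg_reference(leg_torsion_seq(tor, pos(p2), pos(p3)), g)
  m1 <- nrow(leg1); m2 <- nrow(leg2)
  v1 <- leg1[m1, ] - leg1[1, ]; v2 <- leg2[m2, ] - leg2[1, ]
  d12 <- vnorm(v1); d23 <- vnorm(v2)
  Dv <- CA3 - CA1; D <- vnorm(Dv)
  if (D > d12 + d23 - 1e-9 || D < abs(d12 - d23) + 1e-9 || D < 1e-9) {
    # tangent or unreachable: the tangent case is measure-zero; treat the
    # strictly-outside case as no solutions
    if (D > d12 + d23 || D < abs(d12 - d23)) {
      attr(empty, "problem") <- pr
      return(empty)
    }
  }
  uhat <- Dv / D
  cc <- (d12^2 - d23^2 + D^2) / (2 * D)
  rho2 <- d12^2 - cc^2
  rho <- sqrt(max(rho2, 0))
  O <- CA1 + cc * uhat
  ref <- if (abs(uhat[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- vunit(vcross(uhat, ref)); e2 <- vcross(uhat, e1)

  # leg reference points relative to their own start pivot
  a1 <- vunit(v1); a2 <- vunit(v2)
  pC1 <- leg1[2, ] - leg1[1, ]          # C of pivot 1
  pN2 <- leg1[m1 - 1L, ] - leg1[1, ]    # N of pivot 2
  qC2 <- leg2[2, ] - leg2[1, ]          # C of pivot 2
  qN3 <- leg2[m2 - 1L, ] - leg2[1, ]    # N of pivot 3
  nhat <- vunit(N1 - CA1)
  chat <- vunit(C3 - CA3)
  cth1 <- cos(g$n_ca_c * DEG)
  b_c <- vnorm(pC1)          # |C(p1) - CA(p1)|, the CA-C bond
  b_n3 <- vnorm(qN3 - v2)    # |N(p3) - CA(p3)|, the N-CA bond

  # vectorised evaluation of the branch residuals over tau
  eval_tau <- function(tau) {
    n <- length(tau)
    CA2 <- matrix(O, n, 3, byrow = TRUE) + rho * (cos(tau) %o% e1 + sin(tau) %o% e2)
    W1 <- (CA2 - matrix(CA1, n, 3, byrow = TRUE)) / d12
    W2 <- (matrix(CA3, n, 3, byrow = TRUE) - CA2) / d23
    ok_rot <- as.numeric(W1 %*% a1) > -1 + 1e-9 & as.numeric(W2 %*% a2) > -1 + 1e-9

    # leg 1: spin sigma1 about axis W1 through CA1
    qc <- rot_between_apply(a1, W1, pC1)
    qc_par <- mdot(qc, W1); qc_perp <- qc - qc_par * W1; wc <- mcross(W1, qc_perp)
    ph1 <- solve_phase(as.numeric(qc_perp %*% nhat), as.numeric(wc %*% nhat),
                       b_c * cth1 - qc_par * as.numeric(W1 %*% nhat))
    qn <- rot_between_apply(a1, W1, pN2)
    qn_par <- mdot(qn, W1); qn_perp <- qn - qn_par * W1; wn <- mcross(W1, qn_perp)

    # leg 2: spin sigma2 about axis W2 through CA2 (towards CA3)
    q3 <- rot_between_apply(a2, W2, qN3)
    q3_par <- mdot(q3, W2); q3_perp <- q3 - q3_par * W2; w3 <- mcross(W2, q3_perp)
    ph2 <- solve_phase(as.numeric(q3_perp %*% chat), as.numeric(w3 %*% chat),
                       b_n3 * cth1 - (q3_par - d23) * as.numeric(W2 %*% chat))
    q2 <- rot_between_apply(a2, W2, qC2)
    q2_par <- mdot(q2, W2); q2_perp <- q2 - q2_par * W2; w2 <- mcross(W2, q2_perp)

    CA1m <- matrix(CA1, n, 3, byrow = TRUE)
    h <- matrix(NA_real_, n, 4)
    br <- 0L
    for (i1 in 1:2) {
      s1 <- if (i1 == 1) ph1$plus else ph1$minus
      N2 <- CA1m + qn_par * W1 + cos(s1) * qn_perp + sin(s1) * wn
      for (i2 in 1:2) {
        br <- br + 1L
        s2 <- if (i2 == 1) ph2$plus else ph2$minus
        C2 <- CA2 + q2_par * W2 + cos(s2) * q2_perp + sin(s2) * w2
        hh <- mdot(N2 - CA2, C2 - CA2) / (g$n_ca * g$ca_c) - cth1
        hh[!ok_rot | !ph1$ok | !ph2$ok] <- NA_real_
        h[, br] <- hh
      }
    }
    h
  }

  h_scalar <- function(tau, branch) eval_tau(tau)[1, branch]

  tau_grid <- seq(-pi, pi, length.out = n_tau + 1L)[-(n_tau + 1L)]
  H <- eval_tau(tau_grid)
  Hw <- rbind(H, H[1, , drop = FALSE]) # wraparound
  tauw <- c(tau_grid, tau_grid[1] + 2 * pi)

  # collect sign-change brackets for all branches, then refine them together
  # by batched subdivision (each round is one vectorised eval_tau call)
  lo <- hi <- double(); brs <- integer()
  b_grid <- b_val <- b_inv <- b_h <- double(); b_br <- integer()
  roots <- list()
  for (br in 1:4) {
    hcol <- Hw[, br]
    for (i in seq_len(length(tauw) - 1L)) {
      h0 <- hcol[i]; h1 <- hcol[i + 1L]
      if (is.na(h0) || is.na(h1)) next
      if (h0 == 0) {
        roots[[length(roots) + 1L]] <- list(tau = tauw[i], branch = br)
      } else if (h0 * h1 < 0) {
        lo <- c(lo, tauw[i]); hi <- c(hi, tauw[i + 1L]); brs <- c(brs, br)
      }
    }
    # validity-boundary records: where the branch discriminant changes sign
    # between grid points, a root may hide between the last valid point and
    # the boundary; collected here, bisected in one batched pass below
    for (i in seq_len(length(tauw) - 1L)) {
      h0 <- hcol[i]; h1 <- hcol[i + 1L]
      if (is.na(h0) == is.na(h1)) next
      h_in <- if (is.na(h1)) h0 else h1
      if (abs(h_in) > 0.25) next  # h cannot reach zero within one grid step
      b_grid <- c(b_grid, if (is.na(h1)) tauw[i] else tauw[i + 1L])
      b_val <- c(b_val, if (is.na(h1)) tauw[i] else tauw[i + 1L])
      b_inv <- c(b_inv, if (is.na(h1)) tauw[i + 1L] else tauw[i])
      b_br <- c(b_br, br)
      b_h <- c(b_h, h_in)
    }
    # tangency rescue: interior local minima of |h| close to zero
    n_h <- length(hcol) - 1L
    for (i in 2:max(2, n_h - 1L)) {
      h0 <- hcol[i]
      if (is.na(h0) || is.na(hcol[i - 1L]) || is.na(hcol[i + 1L])) next
      if (abs(h0) < 0.02 && abs(h0) <= abs(hcol[i - 1L]) && abs(h0) <= abs(hcol[i + 1L]) &&
          h0 * hcol[i - 1L] > 0 && h0 * hcol[i + 1L] > 0) {
        opt <- tryCatch(
          stats::optimize(function(t) h_scalar(t, br)^2,
                          c(tauw[i - 1L], tauw[i + 1L]), tol = 1e-14),
          error = function(e) NULL)
        # near-tangencies are kept as candidates; the forward-build
        # residual check downstream decides whether they close within tol
        if (!is.null(opt) && !is.na(opt$objective) && opt$objective < 1e-4) {
          roots[[length(roots) + 1L]] <- list(tau = opt$minimum, branch = br)
        }
      }
    }
  }
  if (length(b_val)) {
    # batched bisection of the validity boundaries (one eval per round),
    # then a sign check on the edge interval
    for (bi in 1:28) {
      mid <- (b_val + b_inv) / 2
      Hm <- eval_tau(mid)
      hm <- Hm[cbind(seq_along(mid), b_br)]
      valid <- !is.na(hm)
      b_val[valid] <- mid[valid]
      b_inv[!valid] <- mid[!valid]
    }
    He <- eval_tau(b_val)
    for (k in seq_along(b_val)) {
      h_edge <- He[k, b_br[k]]
      if (is.na(h_edge)) next
      # a boundary where |h| is already tiny is a grazing solution (the
      # spin discriminant vanishes there); keep it as a candidate for the
      # residual check
      if (abs(h_edge) < 0.01) {
        roots[[length(roots) + 1L]] <- list(tau = b_val[k], branch = b_br[k])
      }
      if (b_h[k] * h_edge < 0) {
        intv <- sort(c(b_grid[k], b_val[k]))
        rt <- tryCatch(
          stats::uniroot(function(t) h_scalar(t, b_br[k]), intv, tol = 1e-13)$root,
          error = function(e) NA_real_)
        if (!is.na(rt)) {
          roots[[length(roots) + 1L]] <- list(tau = rt, branch = b_br[k])
        }
      }
    }
  }
  if (length(lo)) {
    npts <- 9L
    for (iter in 1:6) {
      taus <- as.numeric(vapply(seq_along(lo), function(k) {
        seq(lo[k], hi[k], length.out = npts)
      }, numeric(npts)))
      Hr <- eval_tau(taus)
      for (k in seq_along(lo)) {
        hk <- Hr[((k - 1L) * npts + 1L):(k * npts), brs[k]]
        tk <- seq(lo[k], hi[k], length.out = npts)
        sc <- which(!is.na(hk[-npts]) & !is.na(hk[-1]) & hk[-npts] * hk[-1] <= 0)
        if (length(sc)) {
          lo[k] <- tk[sc[1]]; hi[k] <- tk[sc[1] + 1L]
        }
      }
    }
    for (k in seq_along(lo)) {
      roots[[length(roots) + 1L]] <- list(tau = (lo[k] + hi[k]) / 2, branch = brs[k])
    }
  }
  if (!length(roots)) {
    attr(empty, "problem") <- pr
    return(empty)
  }

  # reconstruct pivot torsions for each root and verify by forward rebuild
  place_leg <- function(leg, a_unit, pin, axis_unit, sigma) {
    n_at <- nrow(leg)
    relm <- leg - matrix(leg[1, ], n_at, 3, byrow = TRUE)
    Bm <- matrix(axis_unit, n_at, 3, byrow = TRUE)
    rel0 <- matrix(NA_real_, n_at, 3)
    for (k in seq_len(n_at)) {
      rel0[k, ] <- rot_between_apply(a_unit, matrix(axis_unit, 1, 3), relm[k, ])
    }
    par <- as.numeric(rel0 %*% axis_unit)
    perp <- rel0 - par %o% axis_unit
    wv <- mcross(matrix(axis_unit, n_at, 3, byrow = TRUE), perp)
    matrix(pin, n_at, 3, byrow = TRUE) + par %o% axis_unit +
      cos(sigma) * perp + sin(sigma) * wv
  }

  target <- rbind(bb_xyz(pr$bb, rie + 1L, "N"), bb_xyz(pr$bb, rie + 1L, "CA"),
                  bb_xyz(pr$bb, rie + 1L, "C"))
  # full reconstruction of one candidate (tau, branch): spins, pivot
  # torsions and the verified forward-build residual
  recon <- function(tau, br) {
    i1 <- if (br <= 2) 1L else 2L
    i2 <- if (br %% 2L == 1L) 1L else 2L
    CA2 <- O + rho * (cos(tau) * e1 + sin(tau) * e2)
    u12v <- (CA2 - CA1) / d12
    u23v <- (CA3 - CA2) / d23
    qc <- rot_between_apply(a1, matrix(u12v, 1, 3), pC1)[1, ]
    qc_par <- sum(qc * u12v); qc_perp <- qc - qc_par * u12v; wc <- vcross(u12v, qc_perp)
    ph1 <- solve_phase(sum(qc_perp * nhat), sum(wc * nhat),
                       b_c * cth1 - qc_par * sum(u12v * nhat))
    q3 <- rot_between_apply(a2, matrix(u23v, 1, 3), qN3)[1, ]
    q3_par <- sum(q3 * u23v); q3_perp <- q3 - q3_par * u23v; w3 <- vcross(u23v, q3_perp)
    ph2 <- solve_phase(sum(q3_perp * chat), sum(w3 * chat),
                       b_n3 * cth1 - (q3_par - d23) * sum(u23v * chat))
    if (!ph1$ok || !ph2$ok) return(NULL)
    s1 <- if (i1 == 1) ph1$plus else ph1$minus
    s2 <- if (i2 == 1) ph2$plus else ph2$minus
    L1 <- place_leg(leg1, a1, CA1, u12v, s1)
    L2 <- place_leg(leg2, a2, CA2, u23v, s2)
    n1 <- nrow(L1); n2 <- nrow(L2)
    pv <- c(dihedral_angle(C_pre, N1, CA1, L1[2, ]),
            dihedral_angle(N1, CA1, L1[2, ], L1[3, ]),
            dihedral_angle(L1[n1 - 2L, ], L1[n1 - 1L, ], CA2, L2[2, ]),
            dihedral_angle(L1[n1 - 1L, ], CA2, L2[2, ], L2[3, ]),
            dihedral_angle(L2[n2 - 2L, ], L2[n2 - 1L, ], CA3, C3),
            dihedral_angle(L2[n2 - 1L, ], CA3, C3, N_after))
    full <- tor
    pvpos <- pos(pr$pivots)
    full$phi[pvpos] <- pv[c(1, 3, 5)]
    full$psi[pvpos] <- pv[c(2, 4, 6)]
    built <- rebuild_segment_coords(pr$bb, ri, full$phi, full$psi, full$omega,
                                    g, phi_next)
    list(pv = pv, resid = max(sqrt(rowSums((built$next_ncac - target)^2))))
  }

  # residual vector (9 components) of a pivot-torsion 6-vector, and a short
  # damped Gauss-Newton polish used for grazing candidates whose angle
  # constraint cannot be met exactly on the (tau, sigma) manifold
  pvpos <- pos(pr$pivots)
  resid_vec <- function(pv) {
    full <- tor
    full$phi[pvpos] <- pv[c(1, 3, 5)]
    full$psi[pvpos] <- pv[c(2, 4, 6)]
    built <- rebuild_segment_coords(pr$bb, ri, full$phi, full$psi, full$omega,
                                    g, phi_next)
    as.numeric(built$next_ncac - target)
  }
  resid_max <- function(pv) max(sqrt(rowSums(matrix(resid_vec(pv), 3, 3)^2)))
  gn_polish <- function(pv, iters = 12) {
    best_pv <- pv
    best <- resid_max(pv)
    for (it in seq_len(iters)) {
      r0 <- resid_vec(pv)
      if (max(sqrt(rowSums(matrix(r0, 3, 3)^2))) < 1e-9) break
      J <- matrix(0, 9, 6)
      for (j in 1:6) {
        dp <- pv; dp[j] <- dp[j] + 1e-5
        J[, j] <- (resid_vec(dp) - r0) / 1e-5
      }
      step <- tryCatch(
        solve(crossprod(J) + 1e-10 * diag(6), -crossprod(J, r0)),
        error = function(e) NULL)
      if (is.null(step)) break
      # backtracking: halve the step until the residual improves
      lam <- 1
      repeat {
        cand <- wrap_angle(pv + lam * as.numeric(step))
        rc <- resid_max(cand)
        if (rc < best || lam < 1 / 64) break
        lam <- lam / 2
      }
      if (rc >= best) break
      pv <- cand; best <- rc; best_pv <- pv
    }
    best_pv
  }

  sols <- list()
  for (rt in roots) {
    tau <- rt$tau; br <- rt$branch
    rc <- recon(tau, br)
    if (is.null(rc) || !is.finite(rc$resid)) next
    pv <- rc$pv; resid <- rc$resid
    if (resid >= tol && resid < 0.05) {
      pv <- gn_polish(pv)
      resid <- max(sqrt(rowSums(matrix(resid_vec(pv), 3, 3)^2)))
    }
    if (resid < tol) {
      sols[[length(sols) + 1L]] <- c(tau, br, pv, resid)
    }
  }
  if (!length(sols)) {
    attr(empty, "problem") <- pr
    return(empty)
  }
  sm <- do.call(rbind, sols)
  out <- tibble::tibble(tau = sm[, 1], branch = as.integer(sm[, 2]),
                        phi1 = sm[, 3], psi1 = sm[, 4], phi2 = sm[, 5],
                        psi2 = sm[, 6], phi3 = sm[, 7], psi3 = sm[, 8],
                        closure_residual = sm[, 9])
  out <- out[order(out$tau, out$branch), , drop = FALSE]
  # dedupe near-identical solutions (branch merges, wraparound)
  if (nrow(out) > 1) {
    keep <- rep(TRUE, nrow(out))
    tm <- as.matrix(out[, c("phi1", "psi1", "phi2", "psi2", "phi3", "psi3")])
    for (i in 2:nrow(out)) {
      for (j in seq_len(i - 1)) {
        if (keep[j] && max(abs(wrap_angle(tm[i, ] - tm[j, ]))) < 0.01) {
          keep[i] <- FALSE
          break
        }
      }
    }
    out <- out[keep, , drop = FALSE]
  }
  attr(out, "problem") <- pr
  out
}

#' Apply a closure solution to the structure
#'
#' Rebuilds the problem's segment with the supplied nonpivot torsions and
#' the solution's pivot torsions.
#'
#' @param problem A [closure_problem()].
#' @param solution One row of the tibble returned by [solve_closure()].
#' @return The closed `backbone` tibble.
#' @export
apply_closure_solution <- function(problem, solution) {
  tor <- problem$torsions
  pvpos <- match(problem$pivots, tor$resnum)
  tor$phi[pvpos] <- c(solution$phi1, solution$phi2, solution$phi3)
  tor$psi[pvpos] <- c(solution$psi1, solution$psi2, solution$psi3)
  set_segment_torsions(problem$bb, problem$segment, tor, problem$geometry)
}

#' Screen closure solutions by Ramachandran plausibility
#'
#' Retains solutions whose pivot (phi, psi) pairs all have binned
#' Ramachandran probability above `threshold` for the pivot residue types;
#' input order is preserved.
#'
#' @param solutions Tibble from [solve_closure()].
#' @param pivot_aa Character vector of 3 one-letter codes for the pivots.
#' @param threshold Relative-density floor; 0 retains everything.
#' @param next_aa Optional codes of the residues following each pivot (for
#'   the preproline class).
#' @return The filtered solutions tibble.
#' @export
rama_filter <- function(solutions, pivot_aa, threshold = 1e-4,
                        next_aa = rep(NA_character_, 3)) {
  if (nrow(solutions) == 0) return(solutions)
  classes <- rama_class(pivot_aa, next_aa)
  keep <- vapply(seq_len(nrow(solutions)), function(i) {
    d <- rama_density(
      phi = c(solutions$phi1[i], solutions$phi2[i], solutions$phi3[i]),
      psi = c(solutions$psi1[i], solutions$psi2[i], solutions$psi3[i]),
      class = classes)
    all(d >= threshold)
  }, logical(1))
  solutions[keep, , drop = FALSE]
}
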