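# Torsion extraction and forward kinematics. The forward builder is the
# workhorse of every sampling move: segment coordinates are always derived
# from torsions + idealised internal geometry, never edited in Cartesian
# space.

#' Backbone torsions of a structure
#'
#' Computes standard phi (C-,N,CA,C), psi (N,CA,C,N+) and omega
#' (CA,C,N+,CA+) dihedrals in degrees. Torsions that require a flanking
#' residue absent from the chain are `NA` (flagged, not invented).
#'
#' @param bb A `backbone` tibble.
#' @param segment Optional [segment_spec()]; defaults to all residues.
#' @return A tibble with columns chain, resnum, aa, phi, psi, omega.
#' @export
backbone_torsions <- function(bb, segment = NULL) {
  res <- bb_residues(bb)
  ri <- if (is.null(segment)) seq_len(nrow(res)) else segment_res_idx(bb, segment)
  m <- bb_coords(bb)
  n <- nrow(res)
  has_prev <- ri > 1 & res$chain[pmax(ri - 1, 1)] == res$chain[ri]
  has_next <- ri < n & res$chain[pmin(ri + 1, n)] == res$chain[ri]
  phi <- psi <- omega <- rep(NA_real_, length(ri))
  for (k in seq_along(ri)) {
    i <- ri[k]
    Ni <- m[bb_row(i, "N"), ]; CAi <- m[bb_row(i, "CA"), ]; Ci <- m[bb_row(i, "C"), ]
    if (has_prev[k]) {
      phi[k] <- dihedral_angle(m[bb_row(i - 1, "C"), ], Ni, CAi, Ci)
    }
    if (has_next[k]) {
      Nn <- m[bb_row(i + 1, "N"), ]
      psi[k] <- dihedral_angle(Ni, CAi, Ci, Nn)
      omega[k] <- dihedral_angle(CAi, Ci, Nn, m[bb_row(i + 1, "CA"), ])
    }
  }
  tibble::tibble(chain = res$chain[ri], resnum = res$resnum[ri], aa = res$aa[ri],
                 phi = phi, psi = psi, omega = omega)
}

# Core forward builder. Given the three anchor atoms (N, CA, C of the
# residue preceding the stretch), the anchor's psi/omega, and per-residue
# phi/psi/omega vectors, sequentially places N, CA, C for each residue and
# then O. Returns the 4L x 3 coordinate block plus the virtual next-residue
# N/CA/C (placed with the supplied phi_next), which is what closure residuals
# are measured against.
build_residues <- function(anchor_n, anchor_ca, anchor_c, psi0, omega0,
                           phi, psi, omega, geometry = ideal_geometry(),
                           phi_next = 180) {
  L <- length(phi)
  stopifnot(length(psi) == L, length(omega) == L)
  if (!all(is.finite(c(psi0, omega0, phi, psi, omega, phi_next)))) {
    stop("non-finite torsion passed to forward builder", call. = FALSE)
  }
  g <- geometry
  # torsion sequence along the chain of backbone atoms
  psis <- c(psi0, psi); omegas <- c(omega0, omega)
  atoms <- matrix(NA_real_, 3 * (L + 1), 3)
  a <- anchor_n; b <- anchor_ca; cc <- anchor_c
  for (i in seq_len(L + 1)) {
    Ni <- place_atom(a, b, cc, g$c_n, g$ca_c_n, psis[i])
    CAi <- place_atom(b, cc, Ni, g$n_ca, g$c_n_ca, omegas[i])
    phii <- if (i <= L) phi[i] else phi_next
    Ci <- place_atom(cc, Ni, CAi, g$ca_c, g$n_ca_c, phii)
    atoms[(3 * i - 2):(3 * i), ] <- rbind(Ni, CAi, Ci)
    a <- Ni; b <- CAi; cc <- Ci
  }
  coords <- matrix(NA_real_, 4 * L, 3)
  for (i in seq_len(L)) {
    Ni <- atoms[3 * i - 2, ]; CAi <- atoms[3 * i - 1, ]; Ci <- atoms[3 * i, ]
    Oi <- place_atom(Ni, CAi, Ci, g$c_o, g$ca_c_o, wrap_angle(psi[i] + 180))
    coords[(4 * i - 3):(4 * i), ] <- rbind(Ni, CAi, Ci, Oi)
  }
  list(coords = coords, next_ncac = atoms[(3 * L + 1):(3 * L + 3), , drop = FALSE])
}

#' Build backbone coordinates from torsions
#'
#' Forward kinematics: places residues sequentially from an anchor frame,
#' honouring the supplied bond lengths, angles and dihedrals exactly.
#'
#' @param anchor_frame A list with elements `N`, `CA`, `C` (length-3 seed
#'   coordinates of the anchor residue) and optionally `psi` and `omega`
#'   (torsions linking the anchor to the first built residue; default 180,
#'   i.e. trans-extended). See [default_anchor()].
#' @param torsions A data frame with columns `phi`, `psi`, `omega` (degrees),
#'   one row per residue to build, and optionally `aa`.
#' @param geometry An [ideal_geometry()].
#' @return A tibble of placed atoms (resnum, atom, x, y, z); zero rows when
#'   `torsions` is empty.
#' @export
coords_from_torsions <- function(anchor_frame, torsions, geometry = ideal_geometry()) {
  if (nrow(torsions) == 0) {
    return(tibble::tibble(resnum = integer(), atom = character(),
                          x = double(), y = double(), z = double()))
  }
  psi0 <- anchor_frame$psi %||% 180
  omega0 <- anchor_frame$omega %||% 180
  built <- build_residues(anchor_frame$N, anchor_frame$CA, anchor_frame$C,
                          psi0, omega0,
                          torsions$phi, torsions$psi, torsions$omega, geometry)
  L <- nrow(torsions)
  tibble::tibble(
    resnum = rep(seq_len(L), each = 4),
    atom = rep(BB_ATOMS, L),
    x = built$coords[, 1], y = built$coords[, 2], z = built$coords[, 3]
  )
}

#' Default anchor frame at the origin
#'
#' @param geometry An [ideal_geometry()].
#' @return An anchor frame list usable with [coords_from_torsions()].
#' @export
default_anchor <- function(geometry = ideal_geometry()) {
  g <- geometry
  N <- c(0, 0, 0)
  CA <- c(g$n_ca, 0, 0)
  ang <- g$n_ca_c * DEG
  C <- CA + g$ca_c * c(-cos(ang), sin(ang), 0)
  list(N = N, CA = CA, C = C, psi = 180, omega = 180)
}

#' Build a complete backbone structure from torsions
#'
#' Convenience wrapper used by the fixture generator: builds a single chain
#' from the default anchor, assigning sequence and numbering.
#'
#' @param torsions Data frame with columns `phi`, `psi`, `omega` (degrees)
#'   and optionally `aa`, one row per residue. `phi` of the first residue is
#'   ignored (undefined at the N-terminus); `NA` psi/omega of the last
#'   residue default to 180.
#' @param chain Chain identifier.
#' @param aa Optional one-letter sequence (overrides `torsions$aa`).
#' @param start_resnum First residue number.
#' @param geometry An [ideal_geometry()].
#' @return A `backbone` tibble whose first residue sits at the default
#'   anchor frame at the origin.
#' @export
backbone_from_torsions <- function(torsions, chain = "A", aa = NULL,
                                   start_resnum = 1, geometry = ideal_geometry()) {
  n <- nrow(torsions)
  if (n < 2) stop("need at least 2 residues", call. = FALSE)
  if (is.null(aa)) {
    aa <- if ("aa" %in% names(torsions)) torsions$aa else rep("A", n)
  }
  stopifnot(length(aa) == n)
  g <- geometry
  anchor <- default_anchor(g)
  fix_na <- function(v) ifelse(is.na(v), 180, v)
  psi <- fix_na(torsions$psi)
  omega <- fix_na(torsions$omega)
  phi <- fix_na(torsions$phi)
  built <- build_residues(anchor$N, anchor$CA, anchor$C,
                          psi0 = psi[1], omega0 = omega[1],
                          phi = phi[-1], psi = psi[-1], omega = omega[-1],
                          geometry = g)
  aO <- place_atom(anchor$N, anchor$CA, anchor$C, g$c_o, g$ca_c_o,
                   wrap_angle(psi[1] + 180))
  coords <- rbind(rbind(anchor$N, anchor$CA, anchor$C, aO), built$coords)
  new_backbone(rep(chain, n), seq(start_resnum, length.out = n), aa, coords)
}

# Fast internal segment rebuild: given residue indices `ri` (contiguous,
# preceded by an anchor residue in the same chain) and torsion vectors,
# returns the new 4L x 3 block and the virtual next-residue N/CA/C.
rebuild_segment_coords <- function(bb, ri, phi, psi, omega,
                                   geometry = ideal_geometry(), phi_next = 180) {
  s <- ri[1]
  anchor_n <- bb_xyz(bb, s - 1L, "N")
  anchor_ca <- bb_xyz(bb, s - 1L, "CA")
  anchor_c <- bb_xyz(bb, s - 1L, "C")
  # psi/omega of the anchor residue are measured from the current structure
  # (they involve the segment's first N/CA, which do not move)
  psi0 <- dihedral_angle(anchor_n, anchor_ca, anchor_c, bb_xyz(bb, s, "N"))
  omega0 <- dihedral_angle(anchor_ca, anchor_c, bb_xyz(bb, s, "N"),
                           bb_xyz(bb, s, "CA"))
  build_residues(anchor_n, anchor_ca, anchor_c, psi0, omega0,
                 phi, psi, omega, geometry, phi_next)
}

#' Set segment torsions and rebuild coordinates
#'
#' Applies new phi/psi/omega values to segment residues and rebuilds the
#' segment forward from its upstream anchor by [coords_from_torsions()]
#' kinematics. Atoms outside the segment are untouched, so the operation
#' generally leaves a chain break at the segment's downstream junction (to
#' be closed by KIC or CCD).
#'
#' @param bb A `backbone` tibble.
#' @param segment A [segment_spec()]; the residue before the segment must
#'   exist (it provides the anchor frame).
#' @param torsions Data frame with columns `resnum`, `phi`, `psi`, `omega`;
#'   `NA` entries keep the current value.
#' @param geometry An [ideal_geometry()].
#' @return The modified `backbone` tibble.
#' @export
set_segment_torsions <- function(bb, segment, torsions, geometry = ideal_geometry()) {
  ri <- segment_res_idx(bb, segment)
  if (ri[1] == 1) stop("segment at chain start has no upstream anchor", call. = FALSE)
  cur <- backbone_torsions(bb, segment)
  j <- match(cur$resnum, torsions$resnum)
  phi <- ifelse(!is.na(j) & !is.na(torsions$phi[j]), torsions$phi[j], cur$phi)
  psi <- ifelse(!is.na(j) & !is.na(torsions$psi[j]), torsions$psi[j], cur$psi)
  omega <- ifelse(!is.na(j) & !is.na(torsions$omega[j]), torsions$omega[j], cur$omega)
  if (anyNA(c(phi, psi, omega))) stop("segment torsions incompletely specified", call. = FALSE)
  built <- rebuild_segment_coords(bb, ri, phi, psi, omega, geometry)
  out <- bb_set_coords(bb, built$coords, residue_rows(ri))
  # record the intended torsions as segment state: while the downstream
  # junction is broken, psi/omega of the last residue cannot be recovered
  # from coordinates, so samplers read this state instead of re-measuring
  st <- attr(out, "segment_torsions") %||% list()
  st[[segment_key(segment)]] <- tibble::tibble(resnum = cur$resnum, phi = phi,
                                               psi = psi, omega = omega)
  attr(out, "segment_torsions") <- st
  out
}

segment_key <- function(segment) {
  sprintf("%s:%d-%d", segment$chain, segment$start, segment$end)
}

# Intended torsions of a segment: the state recorded by the last
# set_segment_torsions() call, falling back to measurement from
# coordinates (valid whenever the chain is intact).
segment_torsion_state <- function(bb, segment) {
  st <- attr(bb, "segment_torsions")
  key <- segment_key(segment)
  if (!is.null(st) && key %in% names(st)) return(st[[key]])
  backbone_torsions(bb, segment)[, c("resnum", "phi", "psi", "omega")]
}

# The torsion phi(e+1) of the residue after a segment involves the
# segment's C(e) atom yet belongs to the fixed region: the modeling
# protocol preserves it while the segment is resampled, and closure pins
# the C-side anchor through it. It is captured once when a segment is
# initialised for sampling (while the junction is still intact) and stored
# as the "junction_phi" attribute; all closure code reads it from there,
# falling back to measuring it from current coordinates.
junction_phi_key <- function(segment) paste0(segment$chain, ":", segment$end)

get_junction_phi <- function(bb, segment) {
  jp <- attr(bb, "junction_phi")
  key <- junction_phi_key(segment)
  if (!is.null(jp) && key %in% names(jp)) return(jp[[key]])
  ri <- segment_res_idx(bb, segment)
  e <- ri[length(ri)]
  dihedral_angle(bb_xyz(bb, e, "C"), bb_xyz(bb, e + 1L, "N"),
                 bb_xyz(bb, e + 1L, "CA"), bb_xyz(bb, e + 1L, "C"))
}

set_junction_phi <- function(bb, segment, value) {
  jp <- attr(bb, "junction_phi") %||% c()
  jp[[junction_phi_key(segment)]] <- value
  attr(bb, "junction_phi") <- jp
  bb
}

# Maximum deviation (Angstrom) between the virtual continuation of the
# segment (rebuilt forward from its torsions) and the actual fixed
# downstream N/CA/C of the residue after the segment. `torsions` supplies
# the intended values (measured from the structure when NULL).
closure_residual <- function(bb, segment, geometry = ideal_geometry(),
                             torsions = NULL) {
  ri <- segment_res_idx(bb, segment)
  res <- bb_residues(bb)
  e <- ri[length(ri)]
  if (e >= nrow(res) && is.null(segment)) stop("segment at chain end", call. = FALSE)
  if (e + 1L > nrow(res) || res$chain[e + 1L] != res$chain[e]) {
    stop("segment has no downstream anchor residue", call. = FALSE)
  }
  if (is.null(torsions)) torsions <- segment_torsion_state(bb, segment)
  phi_next <- get_junction_phi(bb, segment)
  built <- rebuild_segment_coords(bb, ri, torsions$phi, torsions$psi,
                                  torsions$omega, geometry, phi_next)
  target <- rbind(bb_xyz(bb, e + 1L, "N"), bb_xyz(bb, e + 1L, "CA"),
                  bb_xyz(bb, e + 1L, "C"))
  max(sqrt(rowSums((built$next_ncac - target)^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
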