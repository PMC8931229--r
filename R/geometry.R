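# Low-level vector geometry shared by all modules. Coordinates are plain
# numeric length-3 vectors or n x 3 matrices in Angstrom; angles are degrees
# at the interfaces and radians internally.

DEG <- pi / 180

#' Wrap angles to the principal interval
#'
#' Maps angles in degrees to `(-180, 180]`, the convention used for all
#' backbone torsions in the package.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, wrapped to `(-180, 180]`.
#' @export
#' @examples
#' wrap_angle(c(190, -180, 540))
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w <= -180 & !is.na(w)] <- 180
  w
}

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector", call. = FALSE)
  v / n
}

vcross <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# Row-wise cross product for n x 3 matrices.
mcross <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

mdot <- function(a, b) rowSums(a * b)

#' Bond angle defined by three points
#'
#' @param a,b,c Length-3 coordinate vectors; the angle is at `b`.
#' @return Angle in degrees in `[0, 180]`.
#' @export
bond_angle <- function(a, b, c) {
  u <- vunit(a - b)
  v <- vunit(c - b)
  acos(max(-1, min(1, sum(u * v)))) / DEG
}

#' Dihedral angle defined by four points
#'
#' Standard IUPAC sign convention: looking down the `b`-`c` bond, a positive
#' angle is a clockwise rotation of `d` relative to `a`.
#'
#' @param a,b,c,d Length-3 coordinate vectors.
#' @return Dihedral in degrees in `(-180, 180]`.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(-atan2(y, x) / DEG)
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Places atom `d` such that `|c-d| = bond`, the angle `b-c-d` equals `angle`
#' and the dihedral `a-b-c-d` equals `torsion`.
#'
#' @param a,b,c Length-3 coordinates of the three reference atoms.
#' @param bond Bond length in Angstrom.
#' @param angle Bond angle in degrees.
#' @param torsion Dihedral in degrees.
#' @return Length-3 coordinate vector for the new atom.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  if (!all(is.finite(c(a, b, c, bond, angle, torsion)))) {
    stop("non-finite input to place_atom", call. = FALSE)
  }
  ang <- angle * DEG
  tor <- torsion * DEG
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Sequentially extend a chain from three seed atoms. `ic` is a data frame /
# list with numeric vectors bond, angle, torsion (degrees). Returns an
# n x 3 matrix of placed atoms in order.
build_chain <- function(seed_a, seed_b, seed_c, bond, angle, torsion) {
  n <- length(bond)
  out <- matrix(NA_real_, n, 3)
  a <- seed_a; b <- seed_b; cc <- seed_c
  for (i in seq_len(n)) {
    d <- place_atom(a, b, cc, bond[i], angle[i], torsion[i])
    out[i, ] <- d
    a <- b; b <- cc; cc <- d
  }
  out
}

# Rotation matrix for rotation by `theta` radians about unit axis k (Rodrigues).
rotation_about_axis <- function(k, theta) {
  k <- vunit(k)
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Rotation matrix mapping unit vector a onto unit vector b (minimal rotation).
rotation_between <- function(a, b) {
  a <- vunit(a); b <- vunit(b)
  v <- vcross(a, b)
  s <- vnorm(v)
  cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to a
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- vunit(vcross(a, ref))
    return(rotation_about_axis(axis, pi))
  }
  rotation_about_axis(v / s, atan2(s, cth))
}

#' Construct a rigid transform
#'
#' A rigid transform is a proper rotation plus translation, applied as
#' `x %*% t(rotation) + translation`.
#'
#' @param rotation 3 x 3 proper orthonormal matrix.
#' @param translation Length-3 numeric vector in Angstrom.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)),
            length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("rotation must be proper orthonormal", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param transform A `rigid_transform`.
#' @param coords n x 3 matrix (or length-3 vector) of coordinates.
#' @return Transformed coordinates, same shape as the input.
#' @export
apply_transform <- function(transform, coords) {
  vec <- is.null(dim(coords))
  m <- if (vec) matrix(coords, 1, 3) else coords
  out <- m %*% t(transform$rotation) +
    matrix(transform$translation, nrow(m), 3, byrow = TRUE)
  if (vec) as.numeric(out) else out
}

#' Invert a rigid transform
#' @param transform A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Compose two rigid transforms
#' @param t1,t2 `rigid_transform` objects; the result applies `t2` first.
#' @return A `rigid_transform` equal to `t1 o t2`.
#' @export
compose_transform <- function(t1, t2) {
  rigid_transform(t1$rotation %*% t2$rotation,
                  as.numeric(t1$rotation %*% t2$translation) + t1$translation)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("rotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 6), collapse = " "), "\n")
  invisible(x)
}

#' Optimal superposition of paired point sets (Kabsch)
#'
#' Computes the least-squares optimal proper rotation and translation mapping
#' `mobile` onto `ref`, and the post-superposition RMSD.
#'
#' @param mobile,ref n x 3 coordinate matrices with paired rows, `n >= 3`.
#' @return A list with elements `transform` (a [rigid_transform()] mapping
#'   mobile onto ref) and `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(mobile, ref) {
  mobile <- as.matrix(mobile); ref <- as.matrix(ref)
  if (nrow(mobile) != nrow(ref)) stop("point sets must be paired", call. = FALSE)
  if (nrow(mobile) < 3) stop("need at least 3 points", call. = FALSE)
  cm <- colMeans(mobile); cr <- colMeans(ref)
  P <- sweep(mobile, 2, cm); Q <- sweep(ref, 2, cr)
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cr - as.numeric(R %*% cm)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(transform = rigid_transform(R, tr), rmsd = rmsd)
}

# Plain coordinate RMSD between paired n x 3 matrices (no superposition).
coord_rmsd <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))
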