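# Backbone structures are tibbles with one row per backbone atom, four atoms
# (N, CA, C, O) per residue in chain order. This flat atom table is the
# universal currency of the package; every modeling function takes it first
# so calls chain with the pipe.

BB_ATOMS <- c("N", "CA", "C", "O")

#' Idealised backbone internal geometry
#'
#' Bond lengths (Angstrom) and bond angles (degrees) used for all
#' internal-coordinate chain building. Defaults are standard idealised
#' values for the peptide backbone.
#'
#' @param n_ca,ca_c,c_n,c_o Bond lengths in Angstrom.
#' @param n_ca_c,ca_c_n,c_n_ca,ca_c_o Bond angles in degrees.
#' @return A named list of class `internal_geometry`.
#' @export
#' @examples
#' ideal_geometry()
ideal_geometry <- function(n_ca = 1.458, ca_c = 1.523, c_n = 1.329, c_o = 1.231,
                           n_ca_c = 111.2, ca_c_n = 116.2, c_n_ca = 121.7,
                           ca_c_o = 120.1) {
  g <- list(n_ca = n_ca, ca_c = ca_c, c_n = c_n, c_o = c_o,
            n_ca_c = n_ca_c, ca_c_n = ca_c_n, c_n_ca = c_n_ca, ca_c_o = ca_c_o)
  lens <- unlist(g[c("n_ca", "ca_c", "c_n", "c_o")])
  angs <- unlist(g[c("n_ca_c", "ca_c_n", "c_n_ca", "ca_c_o")])
  if (any(lens <= 0.8 | lens >= 2)) stop("bond lengths must lie in (0.8, 2) Angstrom", call. = FALSE)
  if (any(angs <= 80 | angs >= 160)) stop("bond angles must lie in (80, 160) degrees", call. = FALSE)
  structure(g, class = "internal_geometry")
}

#' Build a backbone tibble from per-residue records
#'
#' @param chain Character vector of chain identifiers, one per residue.
#' @param resnum Integer vector of 1-based residue numbers (PDB convention).
#' @param aa Character vector of one-letter amino-acid codes.
#' @param coords A `4 * n_res` x 3 matrix of N, CA, C, O coordinates in
#'   residue order.
#' @param validate Check backbone invariants (default `TRUE`).
#' @return A `backbone` tibble with columns chain, resnum, aa, atom, x, y, z.
#' @export
new_backbone <- function(chain, resnum, aa, coords, validate = TRUE) {
  n <- length(resnum)
  stopifnot(length(chain) == n, length(aa) == n, nrow(coords) == 4 * n)
  bb <- tibble::tibble(
    chain = rep(as.character(chain), each = 4),
    resnum = rep(as.integer(resnum), each = 4),
    aa = rep(as.character(aa), each = 4),
    atom = rep(BB_ATOMS, n),
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  )
  bb <- structure(bb, class = c("backbone", class(tibble::tibble())))
  if (validate) validate_backbone(bb)
  bb
}

#' Coerce an atom table to a backbone structure
#'
#' @param x A data frame with columns chain, resnum, aa, atom, x, y, z
#'   containing the four backbone atoms of every residue.
#' @param validate Check backbone invariants (default `TRUE`).
#' @return A `backbone` tibble.
#' @export
as_backbone <- function(x, validate = TRUE) {
  need <- c("chain", "resnum", "aa", "atom", "x", "y", "z")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  x <- tibble::as_tibble(as.data.frame(x)[, need])
  x$resnum <- as.integer(x$resnum)
  key <- paste(x$chain, x$resnum)
  res_order <- unique(key)
  x <- x[order(match(key, res_order), match(x$atom, BB_ATOMS)), ]
  bb <- structure(x, class = c("backbone", class(tibble::tibble())))
  if (validate) validate_backbone(bb)
  bb
}

#' Validate backbone invariants
#'
#' Checks that every residue carries exactly the four backbone atoms with
#' finite coordinates. Returns the structure invisibly; errors name the
#' offending chain/residue.
#'
#' @param bb A `backbone` tibble.
#' @return `bb`, invisibly.
#' @export
validate_backbone <- function(bb) {
  if (nrow(bb) == 0) stop("backbone structure is empty", call. = FALSE)
  key <- paste(bb$chain, bb$resnum)
  for (k in unique(key)) {
    atoms <- bb$atom[key == k]
    if (!identical(sort(atoms), sort(BB_ATOMS))) {
      stop(sprintf("residue %s is missing backbone atom(s): %s",
                   k, paste(setdiff(BB_ATOMS, atoms), collapse = ", ")),
           call. = FALSE)
    }
  }
  if (!all(is.finite(bb$x) & is.finite(bb$y) & is.finite(bb$z))) {
    stop("non-finite coordinates in backbone structure", call. = FALSE)
  }
  invisible(bb)
}

#' Per-residue summary of a backbone structure
#'
#' @param bb A `backbone` tibble.
#' @return A tibble with one row per residue: chain, resnum, aa.
#' @export
bb_residues <- function(bb) {
  i <- which(bb$atom == "CA")
  tibble::tibble(chain = bb$chain[i], resnum = bb$resnum[i], aa = bb$aa[i])
}

#' Coordinate matrix of a backbone structure
#'
#' @param bb A `backbone` tibble.
#' @param rows Optional row indices.
#' @return An n x 3 numeric matrix.
#' @export
bb_coords <- function(bb, rows = NULL) {
  m <- cbind(bb$x, bb$y, bb$z)
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  m
}

# Replace coordinates at `rows` (all rows when NULL).
bb_set_coords <- function(bb, coords, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(bb))
  bb$x[rows] <- coords[, 1]
  bb$y[rows] <- coords[, 2]
  bb$z[rows] <- coords[, 3]
  bb
}

# Row index of `atom` for the residue at residue-index `ri` (position in
# bb_residues order). Relies on the strict N, CA, C, O ordering.
bb_row <- function(ri, atom) (ri - 1L) * 4L + match(atom, BB_ATOMS)

# Coordinates of one atom of one residue (by residue index).
bb_xyz <- function(bb, ri, atom) {
  r <- bb_row(ri, atom)
  c(bb$x[r], bb$y[r], bb$z[r])
}

#' Segment specification
#'
#' A contiguous residue range on one chain, 1-based and inclusive on both
#' ends, matching PDB numbering.
#'
#' @param chain Chain identifier.
#' @param start,end First and last residue numbers (inclusive).
#' @return An object of class `segment_spec`.
#' @export
#' @examples
#' segment_spec("A", 12, 17)
segment_spec <- function(chain, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end) {
    stop("segment requires start <= end", call. = FALSE)
  }
  if (end - start + 1L < 3L) stop("segment must span at least 3 residues", call. = FALSE)
  structure(list(chain = as.character(chain), start = start, end = end),
            class = "segment_spec")
}

#' @export
print.segment_spec <- function(x, ...) {
  cat(sprintf("<segment %s:%d-%d (%d residues)>\n", x$chain, x$start, x$end,
              x$end - x$start + 1L))
  invisible(x)
}

#' Parse a segment string such as "A:34-45"
#' @param x Character scalar of the form `chain:start-end`.
#' @return A [segment_spec()].
#' @export
parse_segment <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4) stop("cannot parse segment spec: ", x, call. = FALSE)
  segment_spec(m[2], as.integer(m[3]), as.integer(m[4]))
}

# Residue indices (positions in bb_residues order) of a segment; errors on
# missing residues.
segment_res_idx <- function(bb, segment) {
  res <- bb_residues(bb)
  want <- seq(segment$start, segment$end)
  idx <- match(paste(segment$chain, want), paste(res$chain, res$resnum))
  if (anyNA(idx)) {
    stop("segment residues absent from structure: ",
         paste(want[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

# Atom row indices for a set of residue indices.
residue_rows <- function(ri) as.vector(t(outer(ri, 1:4, function(i, j) (i - 1L) * 4L + j)))

#' Detect chain breaks
#'
#' Flags consecutive residues within a chain whose peptide C-N distance falls
#' outside 1.33 +/- 0.25 Angstrom. Breaks are reported, never bridged.
#'
#' @param bb A `backbone` tibble.
#' @param tol Half-width of the accepted C-N distance window (Angstrom).
#' @return A tibble with columns chain, resnum (residue before the break) and
#'   cn_dist.
#' @export
chain_breaks <- function(bb, tol = 0.25) {
  res <- bb_residues(bb)
  n <- nrow(res)
  if (n < 2) return(tibble::tibble(chain = character(), resnum = integer(), cn_dist = double()))
  i <- seq_len(n - 1)
  same <- res$chain[i] == res$chain[i + 1]
  cpos <- bb_coords(bb, bb_row(i, "C"))
  npos <- bb_coords(bb, bb_row(i + 1, "N"))
  d <- sqrt(rowSums((cpos - npos)^2))
  bad <- same & abs(d - 1.33) > tol
  tibble::tibble(chain = res$chain[i][bad], resnum = res$resnum[i][bad], cn_dist = d[bad])
}

#' @export
print.backbone <- function(x, ...) {
  res <- bb_residues(x)
  cat(sprintf("# Backbone structure: %d residues, %d atoms, %d chain(s)\n",
              nrow(res), nrow(x), length(unique(res$chain))))
  brk <- chain_breaks(x)
  if (nrow(brk)) cat(sprintf("# Chain breaks after: %s\n",
                             paste(paste0(brk$chain, brk$resnum), collapse = ", ")))
  NextMethod()
}

# One-letter <-> three-letter amino acid helpers (backbone-only model; the
# identity matters for Ramachandran class and fragment picking).
AA1 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
         "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

aa_three <- function(one) {
  out <- AA3[match(toupper(one), AA1)]
  out[is.na(out)] <- "UNK"
  out
}

aa_one <- function(three) {
  out <- AA1[match(toupper(three), AA3)]
  out[is.na(out)] <- "X"
  out
}
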