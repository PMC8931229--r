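# Simplified backbone energy. Three terms - Ramachandran plausibility,
# soft-sphere clash, harmonic coordinate restraints - sufficient to rank
# closed, non-clashing, Ramachandran-plausible loops. No claim of
# comparability to any all-atom force field.

#' Energy term weights
#'
#' @param w_rama,w_clash,w_restraint Non-negative multipliers for the three
#'   energy terms.
#' @return A named list of class `energy_weights`.
#' @export
energy_weights <- function(w_rama = 1, w_clash = 10, w_restraint = 1) {
  w <- list(w_rama = w_rama, w_clash = w_clash, w_restraint = w_restraint)
  if (any(unlist(w) < 0)) stop("energy weights must be >= 0", call. = FALSE)
  structure(w, class = "energy_weights")
}

#' Soft-sphere clash score of a backbone
#'
#' Sum over non-bonded backbone atom pairs (residue separation >= 2, or any
#' inter-chain pair) of `((r0 - d) / r0)^2` for `d < r0`, with `r0` 3.4
#' Angstrom for CA-CA pairs and 3.0 Angstrom otherwise. Zero for clash-free
#' structures; invariant under rigid motion.
#'
#' @param bb A `backbone` tibble.
#' @param r0_ca,r0_other Contact radii in Angstrom.
#' @return Non-negative numeric score.
#' @export
clash_score <- function(bb, r0_ca = 3.4, r0_other = 3.0) {
  m <- bb_coords(bb)
  n <- nrow(m)
  res <- bb_residues(bb)
  ridx <- rep(seq_len(nrow(res)), each = 4L)
  chains <- res$chain[ridx]
  is_ca <- bb$atom == "CA"
  r0max <- max(r0_ca, r0_other)
  d <- as.matrix(stats::dist(m))
  sep_ok <- abs(outer(ridx, ridx, "-")) >= 2L | outer(chains, chains, "!=")
  pair <- upper.tri(d) & sep_ok & d < r0max
  if (!any(pair)) return(0)
  idx <- which(pair, arr.ind = TRUE)
  r0 <- ifelse(is_ca[idx[, 1]] & is_ca[idx[, 2]], r0_ca, r0_other)
  dd <- d[pair]
  sum(ifelse(dd < r0, ((r0 - dd) / r0)^2, 0))
}

#' Construct a harmonic restraint set
#'
#' Each restraint gently pulls one backbone atom toward an ideal position
#' with energy `k * d^2`.
#'
#' @param chain,resnum,atom Atom selectors (vectorised).
#' @param x,y,z Ideal coordinates in Angstrom.
#' @param k Spring constants in energy/Angstrom^2 (default 1, "gently").
#' @return A `restraint_set` tibble.
#' @export
restraint_set <- function(chain, resnum, atom, x, y, z, k = 1) {
  out <- tibble::tibble(chain = as.character(chain), resnum = as.integer(resnum),
                        atom = as.character(atom), x = x, y = y, z = z,
                        k = rep_len(k, length(x)))
  if (any(out$k <= 0)) stop("spring constants must be > 0", call. = FALSE)
  class(out) <- c("restraint_set", class(tibble::tibble()))
  out
}

#' Read restraints from TSV (chain, resnum, atom, x, y, z, k)
#' @param path Input path.
#' @return A `restraint_set`.
#' @export
read_restraints <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  restraint_set(df$chain, df$resnum, df$atom, df$x, df$y, df$z, df$k)
}

#' Write restraints to TSV
#' @param restraints A `restraint_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(restraints, path) {
  utils::write.table(as.data.frame(restraints), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Rows of bb matching each restraint; errors naming unresolved selectors.
resolve_restraints <- function(bb, restraints) {
  key <- paste(bb$chain, bb$resnum, bb$atom)
  want <- paste(restraints$chain, restraints$resnum, restraints$atom)
  rows <- match(want, key)
  if (anyNA(rows)) {
    stop("unresolvable restraint selector(s): ",
         paste(want[is.na(rows)], collapse = "; "), call. = FALSE)
  }
  rows
}

# Distances of restrained atoms to their ideal positions.
restraint_distances <- function(bb, restraints) {
  rows <- resolve_restraints(bb, restraints)
  sqrt((bb$x[rows] - restraints$x)^2 + (bb$y[rows] - restraints$y)^2 +
         (bb$z[rows] - restraints$z)^2)
}

#' Harmonic restraint energy
#'
#' `sum(k * d^2)` over restrained atoms, `d` the distance to the ideal
#' position.
#'
#' @param bb A `backbone` tibble.
#' @param restraints A [restraint_set()] (`NULL` for none).
#' @return Non-negative numeric energy.
#' @export
restraint_energy <- function(bb, restraints) {
  if (is.null(restraints) || nrow(restraints) == 0) return(0)
  sum(restraints$k * restraint_distances(bb, restraints)^2)
}

#' Restraint satisfaction of a model
#'
#' The maximum distance of any restrained atom to its ideal position
#' (Angstrom). Under the design selection rule, < 1 Angstrom counts as a
#' correctly placed functional group and > 2 Angstrom as incorrectly
#' placed.
#'
#' @inheritParams restraint_energy
#' @return Maximum distance in Angstrom (0 for an empty restraint set).
#' @export
restraint_satisfaction <- function(bb, restraints) {
  if (is.null(restraints) || nrow(restraints) == 0) return(0)
  max(restraint_distances(bb, restraints))
}

#' Score a backbone structure
#'
#' Weighted sum of the Ramachandran, clash and restraint terms.
#'
#' @param bb A `backbone` tibble.
#' @param weights An [energy_weights()].
#' @param restraints Optional [restraint_set()].
#' @param rama_segment Optional [segment_spec()] restricting the
#'   Ramachandran term to a region (default: all residues).
#' @return A one-row tibble with columns rama, clash, restraint, total.
#' @export
score_backbone <- function(bb, weights = energy_weights(), restraints = NULL,
                           rama_segment = NULL) {
  r <- suppressWarnings(rama_score(bb, rama_segment))
  cl <- clash_score(bb)
  rs <- restraint_energy(bb, restraints)
  tibble::tibble(rama = r, clash = cl, restraint = rs,
                 total = weights$w_rama * r + weights$w_clash * cl +
                   weights$w_restraint * rs)
}
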