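# Residue-class Ramachandran probability tables. The package ships its own
# synthetic tables: coarse (10 degree bin) probability grids generated from
# a documented parametric mixture of the canonical basins (alpha, beta,
# polyproline-II, left-handed alpha) for four residue classes: general,
# glycine, proline and preproline. Densities are relative to the class
# peak (maximum = 1); bins whose mixture mass falls below a floor are
# exact zeros, defining the disallowed region used for rejection screening.

RAMA_CLASSES <- c("general", "glycine", "proline", "preproline")
RAMA_BIN <- 10
RAMA_ZERO_FLOOR <- 1e-6

rama_basins <- function(class) {
  switch(class,
    general = data.frame(
      phi = c(-63, -118, -65, 57), psi = c(-42, 132, 145, 40),
      sd_phi = c(16, 26, 14, 13), sd_psi = c(14, 22, 16, 13),
      w = c(0.38, 0.42, 0.13, 0.07)),
    glycine = data.frame(
      phi = c(-63, 63, -100, 100), psi = c(-40, 40, 160, -160),
      sd_phi = c(18, 18, 35, 35), sd_psi = c(15, 15, 30, 30),
      w = c(0.22, 0.22, 0.28, 0.28)),
    proline = data.frame(
      phi = c(-63, -63), psi = c(-35, 150),
      sd_phi = c(9, 9), sd_psi = c(13, 16),
      w = c(0.45, 0.55)),
    preproline = data.frame(
      phi = c(-63, -118, -65, 57), psi = c(-42, 135, 145, 40),
      sd_phi = c(16, 26, 14, 13), sd_psi = c(14, 22, 16, 13),
      w = c(0.30, 0.45, 0.20, 0.05)),
    stop("unknown Ramachandran class: ", class, call. = FALSE)
  )
}

.loopforge_env <- new.env(parent = emptyenv())

rama_matrix <- function(class) {
  key <- paste0("rama_", class)
  if (!is.null(.loopforge_env[[key]])) return(.loopforge_env[[key]])
  centers <- seq(-175, 175, by = RAMA_BIN)
  b <- rama_basins(class)
  m <- matrix(0, 36, 36) # phi rows, psi cols
  wdiff <- function(x, mu) {
    d <- abs(x - mu) %% 360
    pmin(d, 360 - d)
  }
  for (k in seq_len(nrow(b))) {
    dphi <- wdiff(centers, b$phi[k]) / b$sd_phi[k]
    dpsi <- wdiff(centers, b$psi[k]) / b$sd_psi[k]
    m <- m + b$w[k] * outer(exp(-0.5 * dphi^2), exp(-0.5 * dpsi^2)) /
      (2 * pi * b$sd_phi[k] * b$sd_psi[k])
  }
  m <- m / sum(m)
  m[m < RAMA_ZERO_FLOOR] <- 0
  # grids are stored relative to the class maximum (peak = 1): thresholds
  # are then fractions of the peak density and comparable across classes
  m <- m / max(m)
  .loopforge_env[[key]] <- m
  m
}

rama_bin_index <- function(angle) {
  pmax(1L, pmin(36L, floor(((angle + 180) %% 360) / RAMA_BIN) + 1L))
}

#' Ramachandran class of a residue
#'
#' @param aa One-letter code(s) of the residue(s).
#' @param next_aa One-letter code(s) of the following residue (`NA` when
#'   unknown); a residue preceding proline is classed `preproline`.
#' @return Character vector of class names.
#' @export
rama_class <- function(aa, next_aa = NA_character_) {
  aa <- toupper(aa)
  if (any(!aa %in% AA1)) {
    stop("unknown amino-acid code: ", paste(setdiff(aa, AA1), collapse = ", "),
         call. = FALSE)
  }
  out <- rep("general", length(aa))
  out[!is.na(next_aa) & toupper(next_aa) == "P"] <- "preproline"
  out[aa == "G"] <- "glycine"
  out[aa == "P"] <- "proline"
  out
}

#' Ramachandran bin probability of torsion pairs
#'
#' Looks up the packaged 10-degree binned table for the residue class;
#' returns the density relative to the class peak (1 at the most probable
#' bin, 0 in disallowed regions).
#'
#' @param phi,psi Torsions in degrees (vectorised).
#' @param class Ramachandran class name(s) (see [rama_class()]), recycled.
#' @return Numeric vector of relative densities in [0, 1].
#' @export
rama_density <- function(phi, psi, class = "general") {
  n <- max(length(phi), length(psi), length(class))
  phi <- rep_len(phi, n); psi <- rep_len(psi, n); class <- rep_len(class, n)
  out <- numeric(n)
  for (cl in unique(class)) {
    m <- rama_matrix(cl)
    i <- which(class == cl)
    out[i] <- m[cbind(rama_bin_index(phi[i]), rama_bin_index(psi[i]))]
  }
  out
}

#' Sample torsion pairs from a Ramachandran table
#'
#' Draws (phi, psi) with probability proportional to the binned density,
#' uniformly within the selected bin.
#'
#' @param n Number of draws.
#' @param class Ramachandran class name.
#' @return A tibble with columns phi, psi (degrees).
#' @export
sample_rama <- function(n, class = "general") {
  m <- rama_matrix(class)
  idx <- sample.int(length(m), n, replace = TRUE, prob = as.numeric(m))
  phi_i <- ((idx - 1) %% 36) + 1
  psi_i <- ((idx - 1) %/% 36) + 1
  centers <- seq(-175, 175, by = RAMA_BIN)
  tibble::tibble(
    phi = wrap_angle(centers[phi_i] + stats::runif(n, -5, 5)),
    psi = wrap_angle(centers[psi_i] + stats::runif(n, -5, 5))
  )
}

#' Ramachandran pseudo-energy of a region
#'
#' Sum over residues of `-log(density)` from the packaged tables; lower is
#' better. Residues whose phi or psi is undefined (chain termini) are
#' skipped with a warning. Zero-density (disallowed) torsions are clamped to
#' a small floor before the log.
#'
#' @param bb A `backbone` tibble.
#' @param segment Optional [segment_spec()] restricting the region; default
#'   all residues.
#' @return Numeric score (0 for an empty region).
#' @export
rama_score <- function(bb, segment = NULL) {
  tor <- backbone_torsions(bb, segment)
  if (nrow(tor) == 0) return(0)
  res <- bb_residues(bb)
  nxt <- res$aa[match(paste(tor$chain, tor$resnum + 1), paste(res$chain, res$resnum))]
  ok <- !is.na(tor$phi) & !is.na(tor$psi)
  if (any(!ok)) {
    warning(sum(!ok), " residue(s) with undefined torsions skipped in rama_score")
  }
  if (!any(ok)) return(0)
  d <- rama_density(tor$phi[ok], tor$psi[ok], rama_class(tor$aa[ok], nxt[ok]))
  sum(-log(pmax(d, 1e-9)))
}

#' Write a Ramachandran table to plain text
#'
#' Serialises the packaged binned grids to a TSV with columns class,
#' phi, psi (bin centers, degrees) and density (relative to class peak).
#'
#' @param path Output file path.
#' @param classes Which classes to write.
#' @return `path`, invisibly.
#' @export
write_rama_table <- function(path, classes = RAMA_CLASSES) {
  centers <- seq(-175, 175, by = RAMA_BIN)
  rows <- purrr::map_dfr(classes, function(cl) {
    m <- rama_matrix(cl)
    tibble::tibble(class = cl,
                   phi = rep(centers, times = 36),
                   psi = rep(centers, each = 36),
                   density = m[cbind(rep(1:36, times = 36), rep(1:36, each = 36))])
  })
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Ramachandran table from plain text
#'
#' Reads a TSV written by [write_rama_table()] and installs the grids as the
#' session's lookup tables.
#'
#' @param path Path to the TSV.
#' @return A tibble of the parsed table, invisibly.
#' @export
read_rama_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  for (cl in unique(tab$class)) {
    sub <- tab[tab$class == cl, ]
    m <- matrix(0, 36, 36)
    m[cbind(rama_bin_index(sub$phi), rama_bin_index(sub$psi))] <- sub$density
    .loopforge_env[[paste0("rama_", cl)]] <- m / max(m)
  }
  invisible(tibble::as_tibble(tab))
}
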