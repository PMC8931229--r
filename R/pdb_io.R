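# PDB reading/writing, delegated to bio3d behind the package's backbone
# tibble representation. Only ATOM records for N/CA/C/O are used; side
# chains, waters and hetero records are ignored.

#' Read a backbone structure from a PDB file
#'
#' Parses ATOM records, keeps the four backbone atoms of each standard
#' residue and returns them as a [new_backbone()] tibble. Hetero records,
#' waters and side-chain atoms are ignored. A missing backbone atom is an
#' error naming the residue, except a missing terminal O which is rebuilt
#' from idealised geometry. Chain breaks (peptide C-N bond outside
#' 1.33 +/- 0.25 Angstrom) are recorded via [chain_breaks()], never bridged.
#'
#' @param path Path to a PDB file.
#' @param model_index Which MODEL to read when the file has several
#'   (default 1).
#' @return A `backbone` tibble.
#' @export
read_pdb <- function(path, model_index = 1) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("could not parse PDB file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety %in% BB_ATOMS, , drop = FALSE]
  if (nrow(at) == 0) stop("no backbone ATOM records in ", path, call. = FALSE)
  if (any(!is.na(at$insert) & at$insert != "")) {
    stop("insertion codes are not supported", call. = FALSE)
  }
  if (model_index > 1) {
    if (model_index > nrow(pdb$xyz)) stop("model_index exceeds models in file", call. = FALSE)
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    keep <- which(pdb$atom$type == "ATOM" & pdb$atom$elety %in% BB_ATOMS)
    at[, c("x", "y", "z")] <- xyz[keep, , drop = FALSE]
  }
  at$chain[is.na(at$chain)] <- "A"

  key <- paste(at$chain, at$resno)
  res_keys <- unique(key)
  n <- length(res_keys)
  chain <- character(n); resnum <- integer(n); aa <- character(n)
  coords <- matrix(NA_real_, 4 * n, 3)
  for (i in seq_len(n)) {
    rows <- at[key == res_keys[i], , drop = FALSE]
    chain[i] <- rows$chain[1]; resnum[i] <- rows$resno[1]
    aa[i] <- aa_one(rows$resid[1])
    missing <- setdiff(BB_ATOMS, rows$elety)
    if (length(missing) && !identical(missing, "O")) {
      stop(sprintf("residue %s %d is missing backbone atom(s): %s",
                   rows$chain[1], rows$resno[1], paste(missing, collapse = ", ")),
           call. = FALSE)
    }
    for (j in 1:4) {
      r <- rows[rows$elety == BB_ATOMS[j], , drop = FALSE]
      if (nrow(r)) coords[(i - 1) * 4 + j, ] <- c(r$x[1], r$y[1], r$z[1])
    }
    if (length(missing)) {
      # terminal O rebuilt trans to the residue's own N about the CA-C axis
      g <- ideal_geometry()
      i0 <- (i - 1) * 4
      coords[i0 + 4, ] <- place_atom(coords[i0 + 1, ], coords[i0 + 2, ],
                                     coords[i0 + 3, ], g$c_o, g$ca_c_o, 180)
    }
  }
  new_backbone(chain, resnum, aa, coords)
}

#' Write a backbone structure to a PDB file
#'
#' Emits minimal ATOM/TER records (occupancy 1.00, B-factor 0.00) through
#' bio3d.
#'
#' @param bb A `backbone` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(bb, path) {
  validate_backbone(bb)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(bb_coords(bb))),
    type = rep("ATOM", nrow(bb)),
    resno = bb$resnum,
    resid = aa_three(bb$aa),
    eleno = seq_len(nrow(bb)),
    elety = bb$atom,
    chain = bb$chain,
    o = rep(1, nrow(bb)),
    b = rep(0, nrow(bb))
  )
  invisible(path)
}
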