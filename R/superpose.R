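# Superposition-based metrics and local residue frames.

#' Segment backbone RMSD between a model and a reference
#'
#' The benchmark metric: when `align_rest` is `TRUE`, the model is first
#' superposed onto the reference using only non-segment backbone atoms, and
#' the RMSD is then computed over the segment's N, CA, C and O atoms. With
#' `align_rest = FALSE` no superposition is performed (the metric is then
#' symmetric in its arguments).
#'
#' @param model,reference `backbone` tibbles sharing residue numbering.
#' @param segments A [segment_spec()] or list of them; multi-segment cases
#'   are measured jointly over all segment atoms after a single alignment.
#' @param align_rest Superpose on non-segment atoms first (default `TRUE`).
#' @param atoms Which backbone atoms enter the RMSD (default all four).
#' @return RMSD in Angstrom.
#' @export
backbone_rmsd <- function(model, reference, segments, align_rest = TRUE,
                          atoms = BB_ATOMS) {
  if (inherits(segments, "segment_spec")) segments <- list(segments)
  res_m <- bb_residues(model); res_r <- bb_residues(reference)
  key_m <- paste(res_m$chain, res_m$resnum); key_r <- paste(res_r$chain, res_r$resnum)
  map <- match(key_m, key_r)
  if (anyNA(map)) {
    stop("residues missing from reference: ",
         paste(key_m[is.na(map)], collapse = ", "), call. = FALSE)
  }
  seg_ri_m <- sort(unique(unlist(lapply(segments, function(s) segment_res_idx(model, s)))))
  seg_ri_r <- map[seg_ri_m]
  seg_rows_m <- residue_rows(seg_ri_m); seg_rows_m <- seg_rows_m[model$atom[seg_rows_m] %in% atoms]
  seg_rows_r <- residue_rows(seg_ri_r); seg_rows_r <- seg_rows_r[reference$atom[seg_rows_r] %in% atoms]
  mm <- bb_coords(model, seg_rows_m)
  mr <- bb_coords(reference, seg_rows_r)
  if (align_rest) {
    rest_ri_m <- setdiff(seq_len(nrow(res_m)), seg_ri_m)
    if (length(rest_ri_m) < 1) stop("no non-segment residues to align on", call. = FALSE)
    rows_m <- residue_rows(rest_ri_m)
    rows_r <- residue_rows(map[rest_ri_m])
    fit <- kabsch_superpose(bb_coords(model, rows_m), bb_coords(reference, rows_r))
    mm <- apply_transform(fit$transform, mm)
  }
  coord_rmsd(mm, mr)
}

# Local orthonormal frame of a residue: origin at CA, x along N->CA,
# remaining axes from the N/CA/C plane. Errors when N, CA, C are collinear.
residue_frame <- function(bb, ri) {
  N <- bb_xyz(bb, ri, "N"); CA <- bb_xyz(bb, ri, "CA"); C <- bb_xyz(bb, ri, "C")
  x <- vunit(CA - N)
  v <- C - CA
  v_perp <- v - sum(v * x) * x
  if (vnorm(v_perp) < 1e-8) stop("degenerate residue frame: N, CA, C collinear", call. = FALSE)
  y <- vunit(v_perp)
  z <- vcross(x, y)
  list(origin = CA, axes = unname(cbind(x, y, z)))
}

#' Rigid transform between two residue frames
#'
#' The 6D transformation mapping the local backbone frame (origin CA, axes
#' from N/CA/C) of residue `resnum_a` onto that of residue `resnum_b`,
#' expressed in the frame of residue a. Used as the loophash query key; it
#' is invariant under global rigid motion of the structure.
#'
#' @param bb A `backbone` tibble.
#' @param resnum_a,resnum_b Residue numbers.
#' @param chain Chain identifier (default first chain).
#' @return A [rigid_transform()].
#' @export
segment_rigid_transform <- function(bb, resnum_a, resnum_b, chain = NULL) {
  res <- bb_residues(bb)
  if (is.null(chain)) chain <- res$chain[1]
  ia <- match(paste(chain, resnum_a), paste(res$chain, res$resnum))
  ib <- match(paste(chain, resnum_b), paste(res$chain, res$resnum))
  if (is.na(ia) || is.na(ib)) stop("residue not found for transform", call. = FALSE)
  fa <- residue_frame(bb, ia)
  fb <- residue_frame(bb, ib)
  Ra <- fa$axes; Rb <- fb$axes
  rot <- unname(t(Ra) %*% Rb)
  tr <- as.numeric(t(Ra) %*% (fb$origin - fa$origin))
  rigid_transform(rot, tr)
}
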