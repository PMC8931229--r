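# Fragment libraries: torsion runs of length 9, 3 or 1 harvested from
# source structures, grouped into alignment frames along the query
# sequence, ranked by sequence similarity. Fragment picking supplies the
# coupled phi/psi/omega degrees of freedom for FKIC moves; the chord
# distance quantifies torsion-space similarity between fragments.

blosum62_matrix <- function() {
  if (is.null(.loopforge_env$blosum62)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    .loopforge_env$blosum62 <- env$BLOSUM62
  }
  .loopforge_env$blosum62
}

#' Build a fragment library for a query sequence
#'
#' For each fragment size and each alignment frame along the query, all
#' torsion-complete windows of the source structures are scored against the
#' query window by a BLOSUM62 similarity sum and the best `max_per_frame`
#' are kept (ties broken by source order, then window position). Sources in
#' `exclude_ids` contribute nothing - the homolog-exclusion regime.
#'
#' @param sources Named list of `backbone` tibbles; names are source ids.
#' @param query_sequence One-letter query sequence (the target segment).
#' @param sizes Fragment sizes, a subset of c(1, 3, 9).
#' @param exclude_ids Source ids to exclude (e.g. homologs of the query).
#' @param max_per_frame Maximum fragments kept per alignment frame.
#' @param seg_offset Offset of query position 1 relative to the target
#'   segment's first residue (negative when the query includes upstream
#'   context so that frames can partially overlap the segment).
#' @return A `fragment_library`: a tibble with one row per fragment
#'   position (size, start, frag, source_id, score, pos, aa, phi, psi,
#'   omega), with the query attached as attribute `query` and the offset
#'   as `seg_offset`.
#' @export
build_fragment_library <- function(sources, query_sequence, sizes = c(3L, 9L),
                                   exclude_ids = character(),
                                   max_per_frame = 200, seg_offset = 0L) {
  sizes <- sort(unique(as.integer(sizes)))
  if (!all(sizes %in% c(1L, 3L, 9L))) stop("sizes must be a subset of {1, 3, 9}", call. = FALSE)
  L <- nchar(query_sequence)
  if (L < min(sizes)) stop("query shorter than the smallest fragment size", call. = FALSE)
  query <- strsplit(toupper(query_sequence), "")[[1]]
  if (is.null(names(sources)) || any(names(sources) == "")) {
    stop("sources must be a named list", call. = FALSE)
  }
  use <- setdiff(names(sources), exclude_ids)
  bl <- blosum62_matrix()

  # harvest torsion-complete windows once per source
  src_tor <- purrr::map(sources[use], function(bb) {
    tor <- backbone_torsions(bb)
    tor[stats::complete.cases(tor[, c("phi", "psi", "omega")]), , drop = FALSE]
  })

  rows <- list()
  for (size in sizes[sizes <= L]) {
    for (start in seq_len(L - size + 1L)) {
      qwin <- query[start:(start + size - 1L)]
      cands <- list()
      for (sid in use) {
        tor <- src_tor[[sid]]
        if (nrow(tor) < size) next
        for (j in seq_len(nrow(tor) - size + 1L)) {
          idx <- j:(j + size - 1L)
          if (tor$resnum[idx[size]] - tor$resnum[idx[1]] != size - 1L) next
          if (length(unique(tor$chain[idx])) != 1L) next
          waa <- tor$aa[idx]
          sc <- sum(bl[cbind(match(qwin, rownames(bl)), match(waa, colnames(bl)))])
          if (is.na(sc)) sc <- -Inf
          cands[[length(cands) + 1L]] <- list(sid = sid, j = j, score = sc, idx = idx)
        }
      }
      if (!length(cands)) next
      scs <- vapply(cands, function(x) x$score, numeric(1))
      ord <- order(-scs, match(vapply(cands, function(x) x$sid, character(1)), use),
                   vapply(cands, function(x) x$j, numeric(1)))
      keep <- ord[seq_len(min(max_per_frame, length(ord)))]
      for (r in seq_along(keep)) {
        cd <- cands[[keep[r]]]
        tor <- src_tor[[cd$sid]]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          size = size, start = start, frag = r, source_id = cd$sid,
          score = cd$score, pos = seq_len(size), aa = tor$aa[cd$idx],
          phi = tor$phi[cd$idx], psi = tor$psi[cd$idx], omega = tor$omega[cd$idx])
      }
    }
  }
  if (!length(rows)) {
    warning("fragment library is empty (all sources excluded or no valid windows)")
    out <- tibble::tibble(size = integer(), start = integer(), frag = integer(),
                          source_id = character(), score = double(),
                          pos = integer(), aa = character(), phi = double(),
                          psi = double(), omega = double())
  } else {
    out <- dplyr::bind_rows(rows)
  }
  attr(out, "query") <- toupper(query_sequence)
  attr(out, "seg_offset") <- as.integer(seg_offset)
  class(out) <- c("fragment_library", class(tibble::tibble()))
  out
}

#' Query sequence with flanking context for a segment
#'
#' Returns the one-letter sequence of the segment extended by up to
#' `context` residues on each side (clipped to the chain), with the
#' matching `seg_offset` for [build_fragment_library()]. Context lets
#' 9-mer frames partially overlap short segments.
#'
#' @param bb A `backbone` tibble.
#' @param segment A [segment_spec()].
#' @param context Residues of flanking context on each side.
#' @return A list with `query` and `seg_offset`.
#' @export
segment_query <- function(bb, segment, context = 3L) {
  res <- bb_residues(bb)
  ri <- segment_res_idx(bb, segment)
  ch <- which(res$chain == segment$chain)
  lo <- max(min(ch), ri[1] - context)
  hi <- min(max(ch), ri[length(ri)] + context)
  list(query = paste(res$aa[lo:hi], collapse = ""),
       seg_offset = as.integer(lo - ri[1]))
}

#' Pick a random fragment from a library
#'
#' Size class, alignment frame and fragment are drawn uniformly in turn,
#' matching the three random choices of an FKIC move. Deterministic given
#' the RNG state.
#'
#' @param library A `fragment_library`.
#' @return A list with `size`, `start` (frame position), `source_id` and
#'   `torsions` (tibble pos, aa, phi, psi, omega).
#' @export
pick_fragment <- function(library) {
  if (nrow(library) == 0) stop("fragment library is empty", call. = FALSE)
  sz <- unique(library$size)
  size <- if (length(sz) == 1L) sz else sample(sz, 1L)
  sub <- library[library$size == size, ]
  starts <- unique(sub$start)
  start <- if (length(starts) == 1L) starts else sample(starts, 1L)
  sub <- sub[sub$start == start, ]
  frs <- unique(sub$frag)
  fr <- if (length(frs) == 1L) frs else sample(frs, 1L)
  sub <- sub[sub$frag == fr, ]
  list(size = size, start = start, source_id = sub$source_id[1],
       torsions = sub[, c("pos", "aa", "phi", "psi", "omega")])
}

#' Apply fragment torsions to a segment
#'
#' The fragment's phi/psi/omega are applied to the residues its alignment
#' frame overlaps (partial overlap applies only the overlapping positions);
#' the segment is rebuilt forward, leaving a chain break at the downstream
#' junction for KIC to close.
#'
#' @param bb A `backbone` tibble.
#' @param segment A [segment_spec()].
#' @param frame_start 1-based frame position in segment coordinates (after
#'   any library `seg_offset`; may be non-positive for frames extending
#'   upstream of the segment).
#' @param fragment Fragment torsions: tibble with pos, phi, psi, omega (as
#'   from [pick_fragment()]`$torsions`).
#' @param geometry An [ideal_geometry()].
#' @return The modified `backbone` tibble.
#' @export
insert_fragment_torsions <- function(bb, segment, frame_start, fragment,
                                     geometry = ideal_geometry()) {
  seg_len <- segment$end - segment$start + 1L
  seg_pos <- frame_start + fragment$pos - 1L # fragment positions in segment coords
  keep <- seg_pos >= 1L & seg_pos <= seg_len
  if (!any(keep)) stop("fragment frame does not overlap the segment", call. = FALSE)
  tor <- tibble::tibble(
    resnum = segment$start + seg_pos[keep] - 1L,
    phi = fragment$phi[keep], psi = fragment$psi[keep], omega = fragment$omega[keep])
  set_segment_torsions(bb, segment, tor, geometry)
}

#' Squared chord distance between two angles
#'
#' `D^2(theta1, theta2) = 2 - 2 cos(theta1 - theta2)`: 0 when the angles
#' match, 4 when they differ by 180 degrees.
#'
#' @param theta1,theta2 Angles in degrees (vectorised).
#' @return Numeric vector in `[0, 4]`.
#' @export
#' @examples
#' chord_distance_sq(0, 90)
chord_distance_sq <- function(theta1, theta2) {
  2 - 2 * cos((theta1 - theta2) * DEG)
}

#' Mean chord fragment distance
#'
#' `<D> = (1/n) sum_i (D^2(phi1_i, phi2_i)/2 + D^2(psi1_i, psi2_i)/2)`,
#' the torsion-space distance between two equal-length fragments; ranges
#' from 0 (identical) to 4 (every angle off by 180 degrees).
#'
#' @param fragment,target Data frames with columns `phi` and `psi`
#'   (degrees) and equal row counts.
#' @return A single number in `[0, 4]`.
#' @export
mean_fragment_distance <- function(fragment, target) {
  if (nrow(fragment) != nrow(target)) {
    stop("fragment and target lengths differ", call. = FALSE)
  }
  mean(0.5 * chord_distance_sq(fragment$phi, target$phi) +
         0.5 * chord_distance_sq(fragment$psi, target$psi))
}

#' Write a fragment library to TSV
#'
#' @param library A `fragment_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragment_library <- function(library, path) {
  df <- as.data.frame(library)
  attr(df, "query") <- NULL
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# query\t", attr(library, "query")), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a fragment library from TSV
#'
#' @param path Path written by [write_fragment_library()].
#' @return A `fragment_library`.
#' @export
read_fragment_library <- function(path) {
  first <- readLines(path, n = 1)
  query <- sub("^# query\t", "", first)
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                          stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  attr(out, "query") <- query
  class(out) <- c("fragment_library", class(tibble::tibble()))
  out
}
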