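# Loophash: a database of loop conformations keyed by the bucketed 6D rigid
# transform between their bounding residues. Queried with the transform
# across a gap, it returns loops that approximately close that gap,
# supplying LHKIC with torsion (and optionally sequence) fragments.

#' Intrinsic z-y-x Euler angles of a rotation matrix
#'
#' @param R 3 x 3 proper rotation matrix.
#' @return Numeric vector `c(alpha, beta, gamma)` in degrees, with
#'   `beta` in `[-90, 90]`.
#' @export
euler_zyx <- function(R) {
  beta <- asin(clamp1(-R[3, 1]))
  if (abs(abs(R[3, 1]) - 1) < 1e-9) {
    # gimbal lock: fold everything into alpha
    alpha <- atan2(-R[1, 2], R[2, 2])
    gamma <- 0
  } else {
    alpha <- atan2(R[2, 1], R[1, 1])
    gamma <- atan2(R[3, 2], R[3, 3])
  }
  c(alpha, beta, gamma) / DEG
}

# 6 bucket indices for a rigid transform (3 translation, 3 rotation).
transform_key <- function(transform, trans_bin = 1, rot_bin = 15) {
  tb <- floor(transform$translation / trans_bin)
  ang <- euler_zyx(transform$rotation)
  rb <- floor(ang / rot_bin)
  as.integer(c(tb, rb))
}

key_string <- function(key) paste(key, collapse = ",")

#' Build a loophash database from source structures
#'
#' Every contiguous window of each requested length whose bounding residues
#' lie inside the chain contributes one entry, keyed by the 6D transform
#' between the residue before and the residue after the window.
#'
#' @param sources Named list of `backbone` tibbles.
#' @param lengths Integer vector of loop lengths (>= 3).
#' @param trans_bin Translation bucket width in Angstrom.
#' @param rot_bin Rotation bucket width in degrees (intrinsic z-y-x Euler
#'   angles).
#' @return A `loophash_db` object.
#' @export
build_loophash_db <- function(sources, lengths, trans_bin = 1, rot_bin = 15) {
  lengths <- sort(unique(as.integer(lengths)))
  if (any(lengths < 3)) stop("loop lengths must be >= 3", call. = FALSE)
  if (is.null(names(sources)) || any(names(sources) == "")) {
    stop("sources must be a named list", call. = FALSE)
  }
  entries <- list()
  for (sid in names(sources)) {
    bb <- sources[[sid]]
    tor <- backbone_torsions(bb)
    res <- bb_residues(bb)
    for (ch in unique(res$chain)) {
      ridx <- which(res$chain == ch)
      n <- length(ridx)
      for (L in lengths) {
        if (n < L + 2) next
        for (i in seq(2, n - L)) {
          win <- ridx[i:(i + L - 1)]
          before <- res$resnum[ridx[i - 1]]
          after <- res$resnum[ridx[i + L]]
          tf <- segment_rigid_transform(bb, before, after, chain = ch)
          key <- transform_key(tf, trans_bin, rot_bin)
          entries[[length(entries) + 1L]] <- list(
            length = L, source_id = sid, chain = ch,
            start_resnum = res$resnum[win[1]], key = key,
            torsions = tibble::tibble(pos = seq_len(L), aa = tor$aa[win],
                                      phi = tor$phi[win], psi = tor$psi[win],
                                      omega = tor$omega[win]))
        }
      }
    }
  }
  if (!length(entries)) warning("loophash database is empty (no valid windows)")
  index <- list()
  for (k in seq_along(entries)) {
    L <- entries[[k]]$length
    ks <- key_string(entries[[k]]$key)
    id <- paste0(L, "|", ks)
    index[[id]] <- c(index[[id]], k)
  }
  structure(list(entries = entries, index = index, lengths = lengths,
                 trans_bin = trans_bin, rot_bin = rot_bin),
            class = "loophash_db")
}

#' @export
print.loophash_db <- function(x, ...) {
  cat(sprintf("<loophash_db: %d entries, lengths %s, %d occupied buckets>\n",
              length(x$entries), paste(x$lengths, collapse = "/"),
              length(x$index)))
  invisible(x)
}

#' Query a loophash database
#'
#' Returns the entries stored in the query bucket and all buckets within
#' `radius` Chebyshev bucket steps in the 6 bucket coordinates (rotation
#' indices wrap).
#'
#' @param db A `loophash_db`.
#' @param transform The query [rigid_transform()] across the gap.
#' @param length Loop length to query.
#' @param radius Neighbourhood radius in bucket steps (default 1).
#' @return A list of matching entries (possibly empty); each has elements
#'   length, source_id, chain, start_resnum, key and torsions.
#' @export
query_loophash <- function(db, transform, length, radius = 1) {
  length <- as.integer(length)
  if (!length %in% db$lengths) {
    stop("length ", length, " not present in loophash database", call. = FALSE)
  }
  key <- transform_key(transform, db$trans_bin, db$rot_bin)
  offs <- seq(-radius, radius)
  n_rot <- as.integer(round(360 / db$rot_bin))
  grid <- expand.grid(offs, offs, offs, offs, offs, offs)
  hits <- integer()
  for (r in seq_len(nrow(grid))) {
    k <- key + as.integer(grid[r, ])
    # wrap the alpha/gamma rotation bins; beta does not wrap
    k[4] <- ((k[4] + n_rot / 2) %% n_rot) - n_rot / 2
    k[6] <- ((k[6] + n_rot / 2) %% n_rot) - n_rot / 2
    id <- paste0(length, "|", key_string(k))
    hits <- c(hits, db$index[[id]])
  }
  db$entries[unique(hits)]
}

#' Apply a loophash entry to a segment
#'
#' Replaces the segment's torsions with the entry's (leaving the downstream
#' chain break for KIC) and, when `mutate` is `TRUE`, also adopts the
#' entry's amino-acid sequence on the remodeled residues.
#'
#' @param bb A `backbone` tibble.
#' @param segment A [segment_spec()]; its length must equal the entry's.
#' @param entry An entry from [query_loophash()].
#' @param mutate Adopt the entry's sequence (default `FALSE`).
#' @param geometry An [ideal_geometry()].
#' @return The modified `backbone` tibble.
#' @export
apply_loop_entry <- function(bb, segment, entry, mutate = FALSE,
                             geometry = ideal_geometry()) {
  L <- segment$end - segment$start + 1L
  if (entry$length != L) {
    stop("entry length ", entry$length, " does not match segment length ", L,
         call. = FALSE)
  }
  tor <- tibble::tibble(resnum = seq(segment$start, segment$end),
                        phi = entry$torsions$phi, psi = entry$torsions$psi,
                        omega = entry$torsions$omega)
  out <- set_segment_torsions(bb, segment, tor, geometry)
  if (mutate) {
    ri <- segment_res_idx(out, segment)
    out$aa[residue_rows(ri)] <- rep(entry$torsions$aa, each = 4L)
  }
  out
}

#' Serialise a loophash database to TSV
#'
#' Versioned plain-text format: a header line with the bucket widths, then
#' one row per entry position at full precision.
#'
#' @param db A `loophash_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loophash <- function(db, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# loophash v1\ttrans_bin=%.17g\trot_bin=%.17g",
                     db$trans_bin, db$rot_bin), con)
  rows <- purrr::imap_dfr(db$entries, function(en, i) {
    tibble::tibble(entry = i, length = en$length, source_id = en$source_id,
                   chain = en$chain, start_resnum = en$start_resnum,
                   key = key_string(en$key), pos = en$torsions$pos,
                   aa = en$torsions$aa,
                   phi = sprintf("%.17g", en$torsions$phi),
                   psi = sprintf("%.17g", en$torsions$psi),
                   omega = sprintf("%.17g", en$torsions$omega))
  })
  utils::write.table(rows, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a loophash database written by [write_loophash()]
#'
#' @param path Input path.
#' @return A `loophash_db`.
#' @export
read_loophash <- function(path) {
  header <- readLines(path, n = 1)
  fields <- strsplit(header, "\t")[[1]]
  trans_bin <- as.numeric(sub("trans_bin=", "", fields[2]))
  rot_bin <- as.numeric(sub("rot_bin=", "", fields[3]))
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                          stringsAsFactors = FALSE,
                          colClasses = c(phi = "numeric", psi = "numeric",
                                         omega = "numeric"))
  entries <- list()
  for (i in sort(unique(df$entry))) {
    sub <- df[df$entry == i, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    entries[[i]] <- list(
      length = sub$length[1], source_id = sub$source_id[1], chain = sub$chain[1],
      start_resnum = sub$start_resnum[1],
      key = as.integer(strsplit(sub$key[1], ",")[[1]]),
      torsions = tibble::tibble(pos = sub$pos, aa = sub$aa, phi = sub$phi,
                                psi = sub$psi, omega = sub$omega))
  }
  index <- list()
  for (k in seq_along(entries)) {
    id <- paste0(entries[[k]]$length, "|", key_string(entries[[k]]$key))
    index[[id]] <- c(index[[id]], k)
  }
  structure(list(entries = entries, index = index,
                 lengths = sort(unique(df$length)),
                 trans_bin = trans_bin, rot_bin = rot_bin),
            class = "loophash_db")
}

# True 6D distance between two transforms in bucket units (translation in
# bucket widths, rotation in Euler-angle bucket widths, wrap-aware); used
# by the linear-scan oracle in tests and exposed for diagnostics.
transform_bucket_distance <- function(t1, t2, trans_bin = 1, rot_bin = 15) {
  dt <- abs(t1$translation - t2$translation) / trans_bin
  a1 <- euler_zyx(t1$rotation); a2 <- euler_zyx(t2$rotation)
  da <- abs(a1 - a2) %% 360
  da <- pmin(da, 360 - da) / rot_bin
  max(c(dt, da))
}
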