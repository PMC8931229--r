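test_that("window counting matches the bounding-residue rule", {
  bb <- random_chain(10, seed = 41)
  db <- build_loophash_db(list(src = bb), lengths = 6)
  expect_equal(length(db$entries), 3L) # windows 2-7, 3-8, 4-9
  expect_equal(sort(vapply(db$entries, function(e) e$start_resnum, integer(1))),
               c(2L, 3L, 4L))
})

test_that("every stored entry retrieves itself by its own key", {
  srcs <- list(a = random_chain(20, seed = 42), b = random_chain(18, seed = 43))
  db <- build_loophash_db(srcs, lengths = c(4, 6))
  for (en in db$entries) {
    tf <- segment_rigid_transform(srcs[[en$source_id]], en$start_resnum - 1L,
                                  en$start_resnum + en$length)
    hits <- query_loophash(db, tf, en$length, radius = 0)
    found <- any(vapply(hits, function(h)
      h$source_id == en$source_id && h$start_resnum == en$start_resnum &&
        h$length == en$length, logical(1)))
    expect_true(found)
  }
})

test_that("hash queries equal a wrap-aware linear scan at bucket level", {
  srcs <- lapply(1:6, function(i) random_chain(25, seed = 50 + i))
  names(srcs) <- paste0("s", 1:6)
  db <- build_loophash_db(srcs, lengths = 5)
  n_rot <- as.integer(360 / db$rot_bin)
  chebyshev <- function(k1, k2) {
    d <- abs(k1 - k2)
    d[c(4, 6)] <- pmin(d[c(4, 6)], n_rot - d[c(4, 6)])
    max(d)
  }
  set.seed(9)
  for (probe in 1:5) {
    src <- sample(names(srcs), 1)
    rn <- sample(3:18, 1)
    tf <- segment_rigid_transform(srcs[[src]], rn, rn + 6L)
    qk <- loopforge:::transform_key(tf, db$trans_bin, db$rot_bin)
    for (radius in 0:1) {
      hits <- query_loophash(db, tf, 5, radius = radius)
      hit_ids <- sort(vapply(hits, function(h)
        paste(h$source_id, h$start_resnum), character(1)))
      scan_ids <- sort(unlist(lapply(db$entries, function(en) {
        if (en$length != 5) return(NULL)
        if (chebyshev(en$key, qk) <= radius) paste(en$source_id, en$start_resnum)
      })))
      expect_identical(hit_ids, as.character(scan_ids))
    }
  }

  far <- rigid_transform(diag(3), c(500, 500, 500))
  expect_length(query_loophash(db, far, 5), 0L)
  expect_error(query_loophash(db, far, 11), "not present")
})

test_that("databases round-trip through the TSV serialisation", {
  srcs <- list(a = random_chain(15, seed = 61))
  db <- build_loophash_db(srcs, lengths = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_loophash(db, path)
  back <- read_loophash(path)
  expect_equal(back$trans_bin, db$trans_bin)
  expect_equal(length(back$entries), length(db$entries))
  for (k in seq_along(db$entries)) {
    expect_identical(back$entries[[k]]$key, db$entries[[k]]$key)
    expect_identical(back$entries[[k]]$torsions$phi, db$entries[[k]]$torsions$phi)
    expect_identical(back$entries[[k]]$torsions$aa, db$entries[[k]]$torsions$aa)
  }
  expect_identical(sort(names(back$index)), sort(names(db$index)))
})

test_that("applying a loop entry replaces torsions and optionally sequence", {
  fx <- loop6()
  seg <- fx$segment
  db <- build_loophash_db(list(native_fix1 = fx$native), lengths = 6)
  tf <- segment_rigid_transform(fx$native, seg$start - 1L, seg$end + 1L)
  hits <- query_loophash(db, tf, 6)
  expect_gt(length(hits), 0)
  entry <- hits[[1]]

  plain <- apply_loop_entry(fx$native, seg, entry, mutate = FALSE)
  st <- loopforge:::segment_torsion_state(plain, seg)
  expect_identical(st$phi, entry$torsions$phi)
  expect_identical(bb_residues(plain)$aa, bb_residues(fx$native)$aa)

  mut <- apply_loop_entry(fx$native, seg, entry, mutate = TRUE)
  ri <- loopforge:::segment_res_idx(mut, seg)
  expect_identical(bb_residues(mut)$aa[ri], entry$torsions$aa)

  wrong <- entry; wrong$length <- 5L
  expect_error(apply_loop_entry(fx$native, seg, wrong), "match")

  # apply + KIC closure gives a closed chain
  pr <- closure_problem(plain, seg, pivots = c(seg$start, seg$start + 3, seg$end))
  sols <- solve_closure(pr)
  expect_gt(nrow(sols), 0)
  closed <- apply_closure_solution(pr, sols[1, ])
  expect_lt(loopforge:::closure_residual(closed, seg), 1e-4)
})

test_that("database construction is deterministic", {
  srcs <- list(a = random_chain(16, seed = 71))
  d1 <- build_loophash_db(srcs, lengths = 4)
  d2 <- build_loophash_db(srcs, lengths = 4)
  expect_identical(d1$index, d2$index)
  expect_identical(d1$entries, d2$entries)
})
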