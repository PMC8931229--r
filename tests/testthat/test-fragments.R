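test_that("a native source dominates its own query and exclusion empties it", {
  fx <- loop6()
  lib <- build_fragment_library(fx$sources["native_fix1"], fx$query,
                                sizes = c(3, 9), seg_offset = fx$offset)
  nat_tor <- backbone_torsions(fx$native)
  res <- bb_residues(fx$native)
  ri <- loopforge:::segment_res_idx(fx$native, fx$segment)
  q0 <- ri[1] + fx$offset - 1 # residue index of query position 0
  for (st in unique(lib$start[lib$size == 3])) {
    top <- lib[lib$size == 3 & lib$start == st & lib$frag == 1, ]
    idx <- q0 + st + top$pos - 1
    expect_lt(max(abs(wrap_angle(top$phi - nat_tor$phi[idx]))), 1e-6)
    expect_lt(max(abs(wrap_angle(top$psi - nat_tor$psi[idx]))), 1e-6)
  }
  expect_warning(
    empty <- build_fragment_library(fx$sources["native_fix1"], fx$query,
                                    sizes = c(3), exclude_ids = "native_fix1"),
    "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("frame ranking matches an exhaustive BLOSUM62 re-scoring", {
  fx <- loop6()
  srcs <- fx$sources[1:3]
  lib <- build_fragment_library(srcs, fx$query, sizes = 3, max_per_frame = 200)
  bl <- loopforge:::blosum62_matrix()
  q <- strsplit(fx$query, "")[[1]]
  for (st in c(1, 4)) {
    qwin <- q[st:(st + 2)]
    # independent enumeration of all windows
    cand <- list()
    for (sid in names(srcs)) {
      tor <- backbone_torsions(srcs[[sid]])
      tor <- tor[stats::complete.cases(tor[, c("phi", "psi", "omega")]), ]
      for (j in seq_len(nrow(tor) - 2)) {
        sc <- sum(bl[cbind(qwin, tor$aa[j:(j + 2)])])
        cand[[length(cand) + 1]] <- data.frame(sid = sid, j = j, score = sc)
      }
    }
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$score, match(cand$sid, names(srcs)), cand$j), ]
    got <- lib[lib$size == 3 & lib$start == st & lib$pos == 1, ]
    expect_equal(got$score, cand$score[seq_len(nrow(got))])
    expect_equal(got$source_id, cand$sid[seq_len(nrow(got))])
  }
})

test_that("fragment picking is uniform and reproducible", {
  # synthetic library: 2 size classes x 3 frames x 5 fragments
  lib <- tidyr::expand_grid(size = c(3L, 9L), start = 1:3, frag = 1:5)
  lib <- dplyr::mutate(lib, source_id = "s", score = 0)
  lib <- tidyr::expand_grid(lib, pos = 1L)
  lib$aa <- "A"; lib$phi <- lib$frag * 10; lib$psi <- -40; lib$omega <- 180
  class(lib) <- c("fragment_library", class(tibble::tibble()))

  one <- lib[lib$size == 3 & lib$start == 1 & lib$frag == 1, ]
  class(one) <- class(lib)
  expect_equal(pick_fragment(one)$size, 3L)

  set.seed(55)
  a <- replicate(5, paste(unlist(pick_fragment(lib)[c("size", "start")]), collapse = "-"))
  set.seed(55)
  b <- replicate(5, paste(unlist(pick_fragment(lib)[c("size", "start")]), collapse = "-"))
  expect_identical(a, b)

  set.seed(77)
  n <- 30000
  keys <- character(n)
  for (i in seq_len(n)) {
    fr <- pick_fragment(lib)
    keys[i] <- paste(fr$size, fr$start, fr$torsions$phi[1] / 10)
  }
  # every (class, frame, fragment) cell uniform within 3 sigma binomial
  freq <- table(factor(keys, levels = unique(paste(
    rep(c(3, 9), each = 15), rep(rep(1:3, each = 5), 2), rep(1:5, 6))))) / n
  p <- 1 / 30
  expect_true(all(abs(freq - p) < 3 * sqrt(p * (1 - p) / n)))

  expect_error(pick_fragment(lib[0, ]), "empty")
})

test_that("fragment insertion is exact at overlapped positions", {
  fx <- loop6()
  seg <- fx$segment
  st0 <- loopforge:::segment_torsion_state(
    set_segment_torsions(fx$native, seg, backbone_torsions(fx$native, seg)), seg)

  # inserting the current torsions leaves coordinates unchanged
  cur_frag <- tibble::tibble(pos = 1:3, phi = st0$phi[2:4], psi = st0$psi[2:4],
                             omega = st0$omega[2:4])
  same <- insert_fragment_torsions(fx$native, seg, 2, cur_frag)
  expect_lt(max(abs(bb_coords(same) - bb_coords(fx$native))), 1e-6)

  # new torsions are adopted bit-exactly at overlapped positions
  frag <- tibble::tibble(pos = 1:3, phi = c(-70, -100, 55),
                         psi = c(120, 10, 40), omega = c(180, 175, -178))
  ins <- insert_fragment_torsions(fx$native, seg, 3, frag)
  st <- loopforge:::segment_torsion_state(ins, seg)
  expect_identical(st$phi[3:5], frag$phi)
  expect_identical(st$psi[3:5], frag$psi)
  expect_identical(st$omega[3:5], frag$omega)

  # partial overlap clips; disjoint frames error
  part <- insert_fragment_torsions(fx$native, seg, -1, frag)
  stp <- loopforge:::segment_torsion_state(part, seg)
  expect_identical(stp$phi[1], frag$phi[3])
  expect_error(insert_fragment_torsions(fx$native, seg, 20, frag), "overlap")

  # after KIC closure the inserted nonpivot torsions survive untouched
  # (whether a given middle pivot admits solutions depends on the geometry,
  # so scan the interior pivots for a solvable decomposition)
  sols <- NULL
  for (mid in (seg$start + 1):(seg$end - 1)) {
    pr <- closure_problem(ins, seg, pivots = c(seg$start, mid, seg$end))
    sols <- solve_closure(pr)
    if (nrow(sols) > 0) break
  }
  expect_gt(nrow(sols), 0)
  closed <- apply_closure_solution(pr, sols[1, ])
  stc <- loopforge:::segment_torsion_state(closed, seg)
  np <- setdiff(3:5, match(pr$pivots, stc$resnum)) # nonpivot inserted positions
  expect_identical(stc$phi[np], frag$phi[np - 2L])
  expect_identical(stc$psi[np], frag$psi[np - 2L])
})

test_that("the chord distance has its stated extremes and formula", {
  expect_equal(chord_distance_sq(33, 33), 0, tolerance = 1e-12)
  expect_equal(chord_distance_sq(-90, 90), 4, tolerance = 1e-12)
  expect_equal(chord_distance_sq(0, 90), 2, tolerance = 1e-12)
})

test_that("the mean fragment distance matches its definition", {
  t1 <- tibble::tibble(phi = c(-60, -120, 50), psi = c(-40, 130, 45))
  expect_equal(mean_fragment_distance(t1, t1), 0, tolerance = 1e-12)
  t2 <- tibble::tibble(phi = t1$phi + 180, psi = t1$psi + 180)
  expect_equal(mean_fragment_distance(t1, t2), 4, tolerance = 1e-12)

  set.seed(12)
  worst <- 0
  for (r in 1:50) {
    a <- tibble::tibble(phi = runif(3, -180, 180), psi = runif(3, -180, 180))
    b <- tibble::tibble(phi = runif(3, -180, 180), psi = runif(3, -180, 180))
    direct <- mean((1 - cos((a$phi - b$phi) * pi / 180)) +
                     (1 - cos((a$psi - b$psi) * pi / 180)))
    got <- mean_fragment_distance(a, b)
    worst <- max(worst, abs(got - direct))
    expect_true(got >= 0 && got <= 4)
    expect_equal(got, mean_fragment_distance(b, a), tolerance = 1e-12)
    shifted <- tibble::tibble(phi = a$phi + 360, psi = a$psi - 360)
    expect_equal(got, mean_fragment_distance(shifted, b), tolerance = 1e-9)
  }
  expect_lt(worst, 1e-12)
  expect_error(mean_fragment_distance(t1, t1[1:2, ]), "length")
})

test_that("libraries round-trip through TSV", {
  fx <- loop6()
  lib <- fx$lib_native
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fragment_library(lib, path)
  back <- read_fragment_library(path)
  expect_equal(attr(back, "query"), attr(lib, "query"))
  expect_equal(as.data.frame(back)[, c("size", "start", "frag", "source_id")],
               as.data.frame(lib)[, c("size", "start", "frag", "source_id")])
  expect_equal(back$phi, lib$phi, tolerance = 1e-12)
})
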