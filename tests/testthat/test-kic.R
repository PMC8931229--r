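test_that("pivot selection fixes the ends and randomises the middle", {
  seg3 <- segment_spec("A", 5, 7)
  expect_equal(select_pivots(seg3), c(5L, 6L, 7L))

  seg12 <- segment_spec("A", 10, 21)
  set.seed(99)
  p1 <- select_pivots(seg12)
  set.seed(99)
  expect_identical(select_pivots(seg12), p1)
  expect_equal(p1[c(1, 3)], c(10L, 21L))

  # middle pivot uniform over the 10 interior residues (exact binomial 3 sigma)
  set.seed(123)
  draws <- replicate(10000, select_pivots(seg12)[2])
  freq <- table(factor(draws, levels = 11:20)) / 10000
  p <- 1 / 10
  sd3 <- 3 * sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(freq - p) < sd3))
})

test_that("closure recovers the native pivot torsions of an intact loop", {
  for (sd in c(1, 7)) {
    pr <- random_closure_problem(sd)
    native <- backbone_torsions(pr$bb, pr$segment)
    pv <- match(pr$pivots, native$resnum)
    nat <- c(rbind(native$phi[pv], native$psi[pv]))
    sols <- solve_closure(pr)
    expect_gt(nrow(sols), 0)
    expect_lte(nrow(sols), 16)
    d <- apply(as.matrix(sols[, 3:8]), 1,
               function(r) max(abs(wrap_angle(r - nat))))
    expect_lt(min(d), 1e-3)
    expect_true(all(sols$closure_residual < 1e-4))
  }
})

test_that("out-of-reach anchors yield an empty solution set", {
  bb <- random_chain(14, seed = 2)
  seg <- segment_spec("A", 5, 10)
  # translate everything downstream of the segment far away
  rows <- which(bb$resnum > 10)
  bb$x[rows] <- bb$x[rows] + 80
  pr <- closure_problem(bb, seg, pivots = c(5, 7, 10),
                        torsions = backbone_torsions(random_chain(14, 2), seg))
  sols <- solve_closure(pr)
  expect_equal(nrow(sols), 0L)
})

test_that("solutions honour the closure contract", {
  pr <- random_closure_problem(4)
  sols <- solve_closure(pr)
  for (i in seq_len(nrow(sols))) {
    closed <- apply_closure_solution(pr, sols[i, ])
    # residual of the applied structure below tolerance
    expect_lt(loopforge:::closure_residual(closed, pr$segment), 1e-4)
    # nonpivot torsion state is bit-identical to the problem input
    st <- loopforge:::segment_torsion_state(closed, pr$segment)
    np <- !(st$resnum %in% pr$pivots)
    expect_identical(st$phi[np], pr$torsions$phi[np])
    expect_identical(st$psi[np], pr$torsions$psi[np])
    expect_identical(st$omega, pr$torsions$omega)
    # coordinates outside the segment untouched
    out <- closed$resnum < pr$segment$start | closed$resnum > pr$segment$end
    expect_identical(bb_coords(closed)[out, ], bb_coords(pr$bb)[out, ])
  }
  # determinism: identical problem gives the identical solution list
  expect_identical(sols, solve_closure(pr))
})

test_that("analytic solutions agree with the multistart oracle", {
  # the full 50-problem sweep runs in the acceptance suite; spot-check here
  for (sd in c(3, 5)) {
    pr <- random_closure_problem(sd)
    sols <- solve_closure(pr)
    mins <- multistart_oracle(pr, n_starts = 150, seed = sd)
    am <- as.matrix(sols[, c("phi1", "psi1", "phi2", "psi2", "phi3", "psi3")])
    expect_equal(nrow(am), length(mins))
    for (m in mins) {
      d <- apply(am, 1, function(r) max(abs(wrap_angle(r - m))))
      expect_lt(min(d), 0.1)
    }
  }
})

test_that("the Ramachandran screen filters pivot torsions as specified", {
  sols <- tibble::tibble(tau = c(0.1, 0.2, 0.3), branch = 1L,
                         phi1 = c(-63, 150, -63), psi1 = c(-42, -150, -42),
                         phi2 = -63, psi2 = -42, phi3 = -118, psi3 = 132,
                         closure_residual = 0)
  aa <- c("A", "L", "K")
  expect_identical(rama_filter(sols, aa, threshold = 0), sols)
  kept <- rama_filter(sols, aa, threshold = 1e-9)
  expect_equal(kept$tau, c(0.1, 0.3)) # the (150, -150) pivot row is removed
  expect_equal(nrow(rama_filter(sols[0, ], aa, 0.5)), 0L)
  expect_error(rama_filter(sols, c("A", "B", "K"), 0.1), "unknown amino-acid")
})

test_that("CCD closes breaks monotonically but perturbs many torsions", {
  fx <- loop6()
  seg <- fx$segment

  # an intact segment is returned unchanged after zero iterations
  res0 <- ccd_close(fx$native, seg, tol = 0.1)
  expect_equal(res0$iterations, 0L)
  expect_lt(res0$break_distance, 0.1)
  expect_equal(bb_coords(res0$structure), bb_coords(fx$native), tolerance = 1e-9)

  # break the junction by inserting decoy torsions, then close
  set.seed(17)
  fr <- pick_fragment(fx$lib_all[fx$lib_all$size == 3, ])
  broken <- insert_fragment_torsions(fx$native, seg, fr$start + fx$offset,
                                     fr$torsions)
  pre <- loopforge:::segment_torsion_state(broken, seg)
  res <- ccd_close(broken, seg, max_iters = 60, tol = 0.05)
  expect_true(all(diff(res$trace) < 1e-9)) # non-increasing break distance
  pre_break <- ccd_close(broken, seg, max_iters = 0, tol = 1e-9)$break_distance
  expect_lt(res$break_distance, pre_break) # strictly improved the break

  post_ccd <- loopforge:::segment_torsion_state(res$structure, seg)
  ccd_changed <- sum(abs(wrap_angle(post_ccd$phi - pre$phi)) > 1e-6) +
    sum(abs(wrap_angle(post_ccd$psi - pre$psi)) > 1e-6)
  expect_gt(ccd_changed, 3)

  # KIC closure of the same break touches only the three pivots
  pr <- closure_problem(broken, seg, pivots = c(seg$start, seg$start + 2, seg$end),
                        torsions = pre)
  sols <- solve_closure(pr)
  expect_gt(nrow(sols), 0)
  closed <- apply_closure_solution(pr, sols[1, ])
  post_kic <- loopforge:::segment_torsion_state(closed, seg)
  kic_changed <- which(abs(wrap_angle(post_kic$phi - pre$phi)) > 1e-6 |
                         abs(wrap_angle(post_kic$psi - pre$psi)) > 1e-6)
  expect_true(all(post_kic$resnum[kic_changed] %in% pr$pivots))
})
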