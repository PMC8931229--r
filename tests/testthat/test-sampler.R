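test_that("segment initialisation erases the native conformation", {
  fx <- loop6()
  ext <- initialize_segment(fx$native, fx$segment)
  st <- loopforge:::segment_torsion_state(ext, fx$segment)
  expect_true(all(st$phi == 180 & st$psi == 180 & st$omega == 180))
  expect_gt(backbone_rmsd(ext, fx$native, fx$segment), 1)
  # downstream junction broken until the first closure
  expect_gt(loopforge:::closure_residual(ext, fx$segment), 0.1)

  set.seed(13)
  r1 <- initialize_segment(fx$native, fx$segment, init = "random")
  set.seed(13)
  r2 <- initialize_segment(fx$native, fx$segment, init = "random")
  expect_identical(bb_coords(r1), bb_coords(r2))
  expect_false(isTRUE(all.equal(bb_coords(r1), bb_coords(ext))))
})

test_that("Metropolis acceptance matches the Boltzmann factor", {
  expect_true(loopforge:::metropolis_accept(-3, 0.5)) # downhill always
  set.seed(19)
  n <- 40000; de <- 0.9; temp <- 1.3
  acc <- mean(replicate(n, loopforge:::metropolis_accept(de, temp)))
  p <- exp(-de / temp)
  expect_lt(abs(acc - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("runs are bit-reproducible and track a non-increasing best energy", {
  fx <- loop6()
  cfg <- sampler_config("fkic", n_models = 2, outer_cycles = 2,
                        inner_cycles = 6, seed = 23)
  e1 <- run_monte_carlo(fx$prep$start, fx$segment, cfg, reference = fx$native,
                        library = fx$lib_native)
  e2 <- run_monte_carlo(fx$prep$start, fx$segment, cfg, reference = fx$native,
                        library = fx$lib_native)
  expect_identical(tidy(e1), tidy(e2))
  for (i in seq_len(nrow(e1$models))) {
    if (!e1$models$failed[i]) {
      expect_identical(bb_coords(e1$models$structure[[i]]),
                       bb_coords(e2$models$structure[[i]]))
      expect_true(all(diff(e1$models$best_trace[[i]]) <= 0))
    }
  }
  gl <- glance(e1)
  expect_equal(gl$n_models, 2L)
  expect_s3_class(autoplot(e1), "ggplot")
})

test_that("every recorded model honours the chain-integrity contract", {
  fx <- loop6()
  cfg <- sampler_config("fkic", n_models = 4, outer_cycles = 2,
                        inner_cycles = 8, seed = 29)
  ens <- run_monte_carlo(fx$prep$start, fx$segment, cfg, reference = fx$native,
                        library = fx$lib_all)
  ok <- !ens$models$failed
  expect_gt(sum(ok), 0)
  out_rows <- fx$prep$start$resnum < fx$segment$start |
    fx$prep$start$resnum > fx$segment$end
  for (i in which(ok)) {
    mdl <- ens$models$structure[[i]]
    expect_lt(ens$models$closure_residual[i], 1e-4)
    expect_identical(bb_coords(mdl)[out_rows, ],
                     bb_coords(fx$prep$start)[out_rows, ])
    # nonpivot torsions equal the last accepted move's sampled values
    info <- ens$models$move_info[[i]]
    st <- loopforge:::segment_torsion_state(mdl, fx$segment)
    np <- !(st$resnum %in% info$pivots)
    expect_identical(st$phi[np], info$torsions$phi[np])
    expect_identical(st$psi[np], info$torsions$psi[np])
  }
})

test_that("FKIC with native fragments recovers the native loop quickly", {
  fx <- loop6()
  cfg <- sampler_config("fkic", n_models = 5, outer_cycles = 4,
                        inner_cycles = 12, seed = 11)
  ens <- run_monte_carlo(fx$prep$start, fx$segment, cfg, reference = fx$native,
                         library = fx$lib_native)
  expect_gte(mean(ens$models$rmsd < 1, na.rm = TRUE), 0.5)
  expect_lt(min(ens$models$rmsd, na.rm = TRUE), 0.5)
})

test_that("LHKIC with a native-only database recovers the native loop", {
  fx <- loop6()
  db <- build_loophash_db(list(native_fix1 = fx$native), lengths = 6)
  cfg <- sampler_config("lhkic", n_models = 3, outer_cycles = 2,
                        inner_cycles = 8, seed = 37)
  ens <- run_monte_carlo(fx$prep$start, fx$segment, cfg, reference = fx$native,
                         db = db)
  expect_true(any(ens$models$rmsd < 1, na.rm = TRUE))

  # mutation adopts the entry sequence
  mv <- NULL
  set.seed(3)
  start <- initialize_segment(fx$prep$start, fx$segment)
  mv <- lhkic_move(start, fx$segment, db,
                   sampler_config("lhkic", seed = 1), mutate = TRUE)
  if (mv$closed) {
    ri <- loopforge:::segment_res_idx(mv$structure, fx$segment)
    expect_identical(bb_residues(mv$structure)$aa[ri], mv$entry$torsions$aa)
  }

  # an empty database rejects every move but the run completes
  empty_db <- suppressWarnings(build_loophash_db(list(tiny = helix_chain(4)),
                                                 lengths = 6))
  cfg2 <- sampler_config("lhkic", n_models = 2, outer_cycles = 1,
                         inner_cycles = 4, seed = 41)
  ens2 <- run_monte_carlo(fx$prep$start, fx$segment, cfg2, db = empty_db)
  expect_true(all(ens2$models$failed))
  expect_true(all(ens2$models$move_failures == 4L))
})

test_that("the CCD baseline mode produces closed models", {
  fx <- loop6()
  cfg <- sampler_config("ccd", n_models = 2, outer_cycles = 1,
                        inner_cycles = 3, seed = 43)
  ens <- run_monte_carlo(fx$prep$start, fx$segment, cfg, reference = fx$native,
                         library = fx$lib_all)
  ok <- !ens$models$failed
  if (any(ok)) {
    expect_true(all(ens$models$closure_residual[ok] < 0.1))
  }
  expect_equal(nrow(ens$models), 2L)
})
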