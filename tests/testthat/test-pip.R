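test_that("pareto_select equals the pairwise-dominance oracle", {
  set.seed(61)
  cands <- tibble::tibble(candidate_id = sprintf("c%03d", 1:200),
                          m1 = runif(200), m2 = runif(200), m3 = runif(200))
  front <- pareto_select(cands, c("m1", "m2", "m3"))

  # independent O(n^2) double-loop dominance oracle
  M <- as.matrix(cands[, c("m1", "m2", "m3")])
  dominated <- rep(FALSE, 200)
  for (i in 1:200) {
    for (j in 1:200) {
      if (i != j && all(M[j, ] <= M[i, ]) && any(M[j, ] < M[i, ])) {
        dominated[i] <- TRUE
        break
      }
    }
  }
  expect_identical(front$candidate_id, cands$candidate_id[!dominated])

  expect_identical(pareto_select(cands[1, ], c("m1", "m2"))$candidate_id, "c001")
  # exact ties on all metrics are both kept
  tied <- tibble::tibble(candidate_id = c("a", "b", "c"),
                         m1 = c(1, 1, 2), m2 = c(2, 2, 3))
  expect_identical(pareto_select(tied, c("m1", "m2"))$candidate_id, c("a", "b"))
  expect_error(pareto_select(cands, c("m1", "nope")), "nope")

  # crowding-distance subsample keeps boundary points
  sub <- pareto_select(cands, c("m1", "m2", "m3"), max_out = 5)
  expect_equal(nrow(sub), 5L)
  expect_true(all(sub$candidate_id %in% front$candidate_id))
})

test_that("boltzmann selection weights candidates by exp(-E/T)", {
  pool <- tibble::tibble(candidate_id = letters[1:5], total = rep(2, 5))
  set.seed(71)
  n <- 10000
  first <- replicate(n, boltzmann_select(pool, 1, 1)$candidate_id)
  freq <- table(factor(first, levels = letters[1:5])) / n
  expect_gt(stats::chisq.test(table(factor(first, levels = letters[1:5])))$p.value,
            1e-4) # uniform when energies are equal
  expect_true(all(abs(freq - 0.2) < 3 * sqrt(0.2 * 0.8 / n)))

  pool2 <- tibble::tibble(candidate_id = letters[1:4], total = c(5, 1, 9, 3))
  set.seed(72)
  cold <- replicate(50, boltzmann_select(pool2, 1e-9, 1)$candidate_id)
  expect_true(all(cold == "b")) # T -> 0: always the minimum-energy candidate

  expect_equal(sort(boltzmann_select(pool2, 1, 4)$candidate_id), letters[1:4])
  expect_error(boltzmann_select(pool2, 1, 5), "pool")
  expect_error(boltzmann_select(pool2, 0, 1), "> 0")
})

test_that("the restraint filter keeps the best per delta, stably", {
  cands <- tibble::tibble(candidate_id = sprintf("x%d", 1:6),
                          delta = c(0, 0, 0, -1, -1, -1),
                          restraint_satisfaction = c(0.2, 1.5, 0.9, 2, 0.1, 0.5))
  kept <- filter_by_restraint_satisfaction(cands, 2)
  expect_setequal(kept$candidate_id[kept$delta == 0], c("x1", "x3"))
  expect_setequal(kept$candidate_id[kept$delta == -1], c("x5", "x6"))
  # monotonicity: kept worst <= discarded best, within delta
  for (d in unique(cands$delta)) {
    k <- kept$restraint_satisfaction[kept$delta == d]
    disc <- setdiff(cands$candidate_id[cands$delta == d],
                    kept$candidate_id[kept$delta == d])
    dv <- cands$restraint_satisfaction[cands$candidate_id %in% disc]
    expect_lte(max(k), min(dv))
  }
  expect_identical(filter_by_restraint_satisfaction(cands, 10), cands)
  expect_error(filter_by_restraint_satisfaction(cands, 0), "> 0")

  # random-pool agreement with a full sort oracle
  set.seed(81)
  pool <- tibble::tibble(candidate_id = sprintf("r%03d", 1:50),
                         delta = 0, restraint_satisfaction = runif(50))
  kept2 <- filter_by_restraint_satisfaction(pool, 7)
  oracle <- pool[order(pool$restraint_satisfaction), ][1:7, ]
  expect_setequal(kept2$candidate_id, oracle$candidate_id)
})

test_that("segment shortening deletes downstream residues and guards restraints", {
  fx <- make_fixture(fixture_spec(loop_length = 8, seed = 6))
  bb <- fx$structure; seg <- fx$segment
  var <- loopforge:::shorten_segment(bb, seg, -2L)
  expect_equal(var$segment$end, seg$end - 2L)
  expect_equal(nrow(bb_residues(var$structure)), nrow(bb_residues(bb)) - 2L)
  expect_false(any(var$structure$resnum %in% c(seg$end - 1L, seg$end)))

  at <- bb[bb$resnum == seg$end & bb$atom == "CA", ]
  rs <- restraint_set("A", seg$end, "CA", at$x, at$y, at$z)
  expect_error(loopforge:::shorten_segment(bb, seg, -1L, rs), "restrained")

  task <- design_task(bb, seg, rs, length_deltas = c(0L, -1L))
  expect_error(design_task(bb, seg, rs, length_deltas = 1L), "0 .. -6")
  expect_error(design_task(bb, segment_spec("A", seg$start, seg$start + 3),
                           rs, length_deltas = -6L), "below 3")
  expect_s3_class(task, "design_task")
})

test_that("restrained generation tags deltas and satisfies easy restraints", {
  fx <- loop6()
  db <- build_loophash_db(c(list(native_fix1 = fx$native), fx$sources[1:2]),
                          lengths = c(5, 6))
  ri <- loopforge:::segment_res_idx(fx$native, fx$segment)
  mid <- ri[3]
  nat <- bb_coords(fx$native, loopforge:::bb_row(mid, "CA"))
  rs <- restraint_set("A", bb_residues(fx$native)$resnum[mid], "CA",
                      nat[1], nat[2], nat[3], k = 1)
  task <- design_task(initialize_segment(fx$native, fx$segment), fx$segment,
                      rs, length_deltas = c(0L, -1L), keep_per_delta = 3L)
  cfg <- sampler_config("lhkic", n_models = 4, outer_cycles = 2,
                        inner_cycles = 6, seed = 51, mutate_on_lhkic = TRUE)
  cands <- generate_restrained_backbones(task, cfg, db = db)
  expect_true(all(cands$delta %in% c(0L, -1L)))
  for (i in seq_len(nrow(cands))) {
    L <- cands$segment[[i]]$end - cands$segment[[i]]$start + 1L
    expect_equal(L, 6L + cands$delta[i])
  }
  # restraints targeting reachable (native) positions are satisfiable
  expect_lt(min(cands$restraint_satisfaction[cands$delta == 0]), 1)

  kept <- filter_by_restraint_satisfaction(cands, 3)
  adopted <- adopt_fragment_sequences(kept, db)
  expect_true(all(nchar(adopted$sequence) ==
                    6L + adopted$delta))
})

test_that("gap analysis partitions models by the two-threshold rule", {
  fx <- loop6()
  ri <- loopforge:::segment_res_idx(fx$native, fx$segment)
  mid <- ri[3]
  nat <- bb_coords(fx$native, loopforge:::bb_row(mid, "CA"))
  rs <- restraint_set("A", bb_residues(fx$native)$resnum[mid], "CA",
                      nat[1], nat[2], nat[3])
  cands <- tibble::tibble(
    candidate_id = "cand1", delta = 0L,
    structure = list(fx$native), segment = list(fx$segment))
  cfg <- sampler_config("fkic", n_models = 6, outer_cycles = 2,
                        inner_cycles = 6, seed = 53)
  pg <- predict_and_gap(cands, rs, cfg, fx$sources)
  rep <- pg$report
  expect_equal(nrow(rep), 1L)

  # scorefile-style recomputation from the returned ensemble
  ens <- pg$ensembles[["cand1"]]
  mods <- ens$models[!ens$models$failed, ]
  sat <- mods$satisfaction < 1
  unsat <- mods$satisfaction > 2
  expect_equal(rep$n_satisfied, sum(sat))
  expect_equal(rep$n_unsatisfied, sum(unsat))
  if (any(sat) && any(unsat)) {
    expect_equal(rep$gap, min(mods$total[unsat]) - min(mods$total[sat]))
    expect_true(rep$gap_defined)
  } else {
    expect_false(rep$gap_defined)
  }
  expect_equal(rep$lowest_energy_satisfied, sat[which.min(mods$total)])
})
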