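test_that("PDB round trip preserves the backbone", {
  fx <- make_fixture(fixture_spec(loop_length = 5, seed = 2))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(fx$structure, path)
  back <- read_pdb(path)
  expect_equal(nrow(back), nrow(fx$structure))
  expect_equal(bb_residues(back), bb_residues(fx$structure))
  expect_lt(max(abs(bb_coords(back) - bb_coords(fx$structure))), 1e-3)
})

test_that("reading keeps residue counts and rejects incomplete residues", {
  hx <- helix_chain(10)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(hx, path)
  bb <- read_pdb(path)
  expect_equal(nrow(bb_residues(bb)), 10L)
  expect_equal(nrow(bb), 40L)

  # drop the CA of residue 4: the reader must name the residue
  lines <- readLines(path)
  ca4 <- grepl("^ATOM", lines) & grepl(" CA ", lines) & grepl(" {3}4 ", lines)
  writeLines(lines[!ca4], path)
  expect_error(read_pdb(path), "4.*CA|CA.*4")

  expect_error(read_pdb(withr::local_tempfile(fileext = ".pdb")), "exist")
})

test_that("torsion extraction matches construction and flags termini", {
  hx <- helix_chain(10)
  tor <- backbone_torsions(hx)
  expect_true(all(abs(tor$phi[-1] + 57) < 1))
  expect_true(all(abs(tor$psi[-10] + 47) < 1))
  expect_true(is.na(tor$phi[1]))   # no upstream residue: flagged, not invented
  expect_true(is.na(tor$psi[10]))

  # analytic four-point dihedral at 90 degrees
  a <- c(0, 0, 0); b <- c(1, 0, 0); cc <- c(1, 1, 0)
  d <- place_atom(a, b, cc, 1.5, 109, 90)
  expect_equal(dihedral_angle(a, b, cc, d), 90, tolerance = 1e-6)
})

test_that("torsion round trip through forward kinematics is exact", {
  set.seed(21)
  worst <- 0
  for (rep in 1:20) {
    n <- 52
    tor <- tibble::tibble(phi = runif(n, -180, 180), psi = runif(n, -180, 180),
                          omega = runif(n, -180, 180))
    bb <- backbone_from_torsions(tor)
    got <- backbone_torsions(bb)
    mid <- 2:(n - 1)
    worst <- max(worst,
                 abs(wrap_angle(got$phi[mid] - tor$phi[mid])),
                 abs(wrap_angle(got$psi[mid] - tor$psi[mid])),
                 abs(wrap_angle(got$omega[mid - 1] - tor$omega[mid - 1])))
  }
  expect_lt(worst, 1e-6) # 1000 random triplets round-tripped
})

test_that("forward building honours extended geometry and empty input", {
  ext <- coords_from_torsions(default_anchor(),
                              tibble::tibble(phi = rep(180, 6), psi = rep(180, 6),
                                             omega = rep(180, 6)))
  ca <- as.matrix(ext[ext$atom == "CA", c("x", "y", "z")])
  d <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(d - 3.80) < 0.05))

  none <- coords_from_torsions(default_anchor(),
                               tibble::tibble(phi = double(), psi = double(),
                                              omega = double()))
  expect_equal(nrow(none), 0L)

  expect_error(coords_from_torsions(default_anchor(),
                                    tibble::tibble(phi = NaN, psi = 1, omega = 1)),
               "finite")
})

test_that("a segment rebuilt from its own torsions reproduces the native", {
  fx <- loop6()
  tor <- backbone_torsions(fx$native, fx$segment)
  rebuilt <- set_segment_torsions(fx$native, fx$segment, tor)
  expect_lt(max(abs(bb_coords(rebuilt) - bb_coords(fx$native))), 0.1)
})

test_that("Kabsch superposition is optimal and rigid-motion invariant", {
  set.seed(4)
  P <- matrix(rnorm(24), 8, 3)

  fit0 <- kabsch_superpose(P, P)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit0$transform$rotation, diag(3), tolerance = 1e-9)

  th <- 37 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Q <- P %*% t(Rz) + matrix(c(1, -2, 5), 8, 3, byrow = TRUE)
  expect_lt(kabsch_superpose(P, Q)$rmsd, 1e-9)

  # optimality against brute-force random rotations
  Q2 <- matrix(rnorm(24), 8, 3)
  best <- kabsch_superpose(P, Q2)$rmsd
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q2, 2, colMeans(Q2))
  brute <- Inf
  for (k in 1:10000) {
    A <- matrix(rnorm(9), 3, 3)
    qr_d <- qr(A); R <- qr.Q(qr_d)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    brute <- min(brute, sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2))))
  }
  expect_lte(best, brute + 1e-12)

  expect_error(kabsch_superpose(P[1:2, ], Q2[1:2, ]), "3 points")
})

test_that("segment backbone RMSD follows its definition", {
  fx <- loop6()
  seg <- fx$segment
  expect_equal(backbone_rmsd(fx$native, fx$native, seg), 0, tolerance = 1e-12)

  # rigid 2 A displacement of the segment with the rest fixed
  shifted <- fx$native
  rows <- loopforge:::residue_rows(loopforge:::segment_res_idx(fx$native, seg))
  shifted$x[rows] <- shifted$x[rows] + 2
  expect_equal(backbone_rmsd(shifted, fx$native, seg), 2, tolerance = 1e-9)

  # independent direct-formula recomputation on a 5-residue segment
  seg5 <- segment_spec("A", seg$start, seg$start + 4)
  mod <- fx$native
  set.seed(8)
  rows5 <- loopforge:::residue_rows(loopforge:::segment_res_idx(mod, seg5))
  mod$x[rows5] <- mod$x[rows5] + rnorm(length(rows5), sd = 0.3)
  mod$y[rows5] <- mod$y[rows5] + rnorm(length(rows5), sd = 0.3)
  direct <- sqrt(mean(rowSums((bb_coords(mod, rows5) -
                                 bb_coords(fx$native, rows5))^2)))
  expect_equal(backbone_rmsd(mod, fx$native, seg5, align_rest = TRUE), direct,
               tolerance = 1e-6) # non-segment atoms identical -> identity fit

  # symmetric without alignment
  expect_equal(backbone_rmsd(mod, fx$native, seg5, align_rest = FALSE),
               backbone_rmsd(fx$native, mod, seg5, align_rest = FALSE),
               tolerance = 1e-12)

  bad <- fx$native[fx$native$resnum != seg$start, ]
  expect_error(backbone_rmsd(fx$native, as_backbone(bad, validate = FALSE), seg),
               "missing")
})

test_that("residue-frame rigid transforms are internal coordinates", {
  bb <- random_chain(12, seed = 6)
  tf_self <- segment_rigid_transform(bb, 4, 4)
  expect_equal(tf_self$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tf_self$translation, c(0, 0, 0), tolerance = 1e-9)

  tf <- segment_rigid_transform(bb, 3, 9)
  # global rigid motion leaves the transform unchanged
  R <- rotation_about_axis(c(1, 2, 3), 0.83)
  moved <- loopforge:::bb_set_coords(bb, bb_coords(bb) %*% t(R) +
                                       matrix(c(4, 5, -6), nrow(bb), 3, byrow = TRUE))
  tf2 <- segment_rigid_transform(moved, 3, 9)
  expect_equal(tf$rotation, tf2$rotation, tolerance = 1e-9)
  expect_equal(tf$translation, tf2$translation, tolerance = 1e-9)

  # forward application: frame_a composed with the transform lands on frame_b
  fa <- loopforge:::residue_frame(bb, 3)
  fb <- loopforge:::residue_frame(bb, 9)
  origin_b <- fa$origin + as.numeric(fa$axes %*% tf$translation)
  expect_equal(origin_b, fb$origin, tolerance = 1e-9)
  expect_equal(fa$axes %*% tf$rotation, fb$axes, tolerance = 1e-9)
})

test_that("chain breaks are detected and never bridged", {
  fx <- make_fixture(fixture_spec(loop_length = 4, seed = 5))
  expect_equal(nrow(chain_breaks(fx$structure)), 0L)
  start <- initialize_segment(fx$structure, fx$segment)
  brk <- chain_breaks(start)
  expect_gte(nrow(brk), 1L)
  expect_true(fx$segment$end %in% brk$resnum)
})
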