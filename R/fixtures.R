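# Programmatic mini-protein fixtures: helical/strand scaffolds flanking
# irregular loop segments with known native conformations. These stand in
# for the PDB-derived benchmark sets; they are synthetic by construction
# and every test input is generated by this module at run time.

FIXTURE_ALPHABET <- c("A", "D", "E", "F", "I", "K", "L", "S")

# fixed aperiodic pattern over the reduced alphabet (every 3-mer distinct),
# so sequence-based fragment picking has an unambiguous signal
FIXTURE_PATTERN <- paste0(
  "ADEKAFAIDFKKKSDIDLELALLFDFDEFIFAKKDDEDELKASADSELIF",
  "KAAEDDSFIKSIKEAKDFLDIAEFSSFASDSDDAKLLIKDSISFLEFADA")

fixture_sequence <- function(n, offset = 0) {
  pat <- strsplit(FIXTURE_PATTERN, "")[[1]]
  pat[((seq_len(n) - 1 + offset) %% length(pat)) + 1]
}

HELIX_PHI <- -57; HELIX_PSI <- -47
STRAND_PHI <- -120; STRAND_PSI <- 130

#' Fixture specification
#'
#' @param loop_length Loop length (4-16 residues).
#' @param flank1,flank2 Lengths of the flanking scaffold elements.
#' @param scaffold `"helix"` or `"strand"` flanks.
#' @param recipe Loop torsion recipe: `"irregular"` (seeded Ramachandran
#'   draws from the general class, redrawn until clash-free) or
#'   `"extended"`.
#' @param seed Seed controlling the loop draw.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(loop_length = 6, flank1 = 8, flank2 = 8,
                         scaffold = c("helix", "strand"),
                         recipe = c("irregular", "extended"), seed = 1) {
  scaffold <- match.arg(scaffold)
  recipe <- match.arg(recipe)
  if (loop_length < 4 || loop_length > 16) {
    stop("loop_length must be between 4 and 16", call. = FALSE)
  }
  if (flank1 < 3 || flank2 < 3) stop("flanks must have >= 3 residues", call. = FALSE)
  structure(list(loop_length = as.integer(loop_length),
                 flank1 = as.integer(flank1), flank2 = as.integer(flank2),
                 scaffold = scaffold, recipe = recipe, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a mini-protein fixture
#'
#' Builds a flank-loop-flank backbone by forward kinematics (so the loop is
#' geometrically closed by construction) and returns it with the loop's
#' [segment_spec()]. Random loop recipes are redrawn (up to `max_retry`
#' times) until the clash score is below 0.1.
#'
#' @param spec A [fixture_spec()].
#' @param max_retry Redraw cap for clashing random loops.
#' @return A list with `structure` (a `backbone`) and `segment`.
#' @export
make_fixture <- function(spec, max_retry = 50) {
  set.seed(spec$seed)
  fl <- if (spec$scaffold == "helix") c(HELIX_PHI, HELIX_PSI) else c(STRAND_PHI, STRAND_PSI)
  n <- spec$flank1 + spec$loop_length + spec$flank2
  loop_rows <- seq(spec$flank1 + 1L, spec$flank1 + spec$loop_length)
  for (attempt in seq_len(max_retry)) {
    loop <- switch(spec$recipe,
      irregular = sample_rama(spec$loop_length, "general"),
      extended = tibble::tibble(phi = rep(180, spec$loop_length),
                                psi = rep(180, spec$loop_length)))
    tor <- tibble::tibble(
      phi = rep(fl[1], n), psi = rep(fl[2], n), omega = 180,
      aa = fixture_sequence(n))
    tor$phi[loop_rows] <- loop$phi
    tor$psi[loop_rows] <- loop$psi
    bb <- backbone_from_torsions(tor)
    if (clash_score(bb) < 0.1) {
      return(list(structure = bb,
                  segment = segment_spec("A", loop_rows[1], loop_rows[length(loop_rows)])))
    }
  }
  stop("could not generate a clash-free fixture in ", max_retry, " attempts",
       call. = FALSE)
}

#' Generate a benchmark set of fixture cases
#'
#' Builds `n_cases` single-segment cases with the requested loop lengths
#' plus optionally `n_two_segment` cases carrying two loops in contact
#' (at least one inter-segment CA pair within 8 Angstrom), patterned on the
#' shapes of loop-modeling benchmark sets. Optionally writes native PDBs
#' and a YAML manifest.
#'
#' @param n_cases Number of single-segment cases.
#' @param lengths Loop lengths, recycled across cases.
#' @param seed Master seed (case i uses `seed + i`).
#' @param n_two_segment Number of two-segment cases (default 0).
#' @param two_segment_length Loop length for two-segment cases.
#' @param dir Optional output directory for PDBs + `manifest.yaml`.
#' @return A list of cases; each has `case_id`, `native` (a `backbone`)
#'   and `segments` (list of [segment_spec()]).
#' @export
make_benchmark_set <- function(n_cases, lengths = 6, seed = 1,
                               n_two_segment = 0, two_segment_length = 6,
                               dir = NULL) {
  if (n_cases < 1 && n_two_segment < 1) stop("need at least one case", call. = FALSE)
  lengths <- rep_len(lengths, max(n_cases, 1))
  cases <- list()
  for (i in seq_len(n_cases)) {
    fx <- make_fixture(fixture_spec(loop_length = lengths[i], seed = seed + i))
    cases[[length(cases) + 1L]] <- list(
      case_id = sprintf("case%02d", i), native = fx$structure,
      segments = list(fx$segment))
  }
  for (j in seq_len(n_two_segment)) {
    cases[[length(cases) + 1L]] <- make_two_segment_case(
      sprintf("pair%02d", j), two_segment_length, seed = seed + 1000L + j)
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    manifest <- lapply(cases, function(cs) {
      pdb <- file.path(dir, paste0(cs$case_id, ".pdb"))
      write_pdb(cs$native, pdb)
      list(case_id = cs$case_id, pdb = basename(pdb),
           segments = vapply(cs$segments, function(s)
             sprintf("%s:%d-%d", s$chain, s$start, s$end), character(1)))
    })
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  }
  cases
}

# Two interacting loops on one chain: flank - loop1 - short helical turn -
# loop2 - flank; redrawn until clash-free and in contact.
make_two_segment_case <- function(case_id, loop_length, seed,
                                  max_retry = 200) {
  set.seed(seed)
  f1 <- 6L; mid <- 5L; f2 <- 6L
  n <- f1 + loop_length + mid + loop_length + f2
  l1 <- seq(f1 + 1L, f1 + loop_length)
  l2 <- seq(f1 + loop_length + mid + 1L, f1 + loop_length + mid + loop_length)
  for (attempt in seq_len(max_retry)) {
    tor <- tibble::tibble(phi = rep(HELIX_PHI, n), psi = rep(HELIX_PSI, n),
                          omega = 180, aa = fixture_sequence(n))
    d1 <- sample_rama(loop_length, "general")
    d2 <- sample_rama(loop_length, "general")
    tor$phi[l1] <- d1$phi; tor$psi[l1] <- d1$psi
    tor$phi[l2] <- d2$phi; tor$psi[l2] <- d2$psi
    bb <- backbone_from_torsions(tor)
    if (clash_score(bb) >= 0.1) next
    ca1 <- bb_coords(bb, bb_row(l1, "CA"))
    ca2 <- bb_coords(bb, bb_row(l2, "CA"))
    dmin <- min(sqrt(outer(rowSums(ca1^2), rowSums(ca2^2), "+") -
                       2 * ca1 %*% t(ca2)))
    if (dmin < 8) {
      return(list(case_id = case_id, native = bb,
                  segments = list(segment_spec("A", l1[1], l1[loop_length]),
                                  segment_spec("A", l2[1], l2[loop_length]))))
    }
  }
  stop("could not generate a contacting two-segment case in ", max_retry,
       " attempts", call. = FALSE)
}

#' Generate noisy homolog copies of a structure
#'
#' Returns copies of `bb` whose torsions carry wrapped Gaussian noise of
#' standard deviation `sigma` degrees, rebuilt by forward kinematics. A
#' family of such homologs provides fragment sources of controlled quality:
#' the mean fragment distance of the resulting libraries grows with
#' `sigma`, the degraded-library regime used in the fragment-quality
#' correlation analysis.
#'
#' @param bb The source `backbone`.
#' @param n Number of noisy copies.
#' @param sigma Torsion noise standard deviation in degrees.
#' @param seed Master seed (copy i uses `seed + i`).
#' @param prefix Source id prefix.
#' @return A named list of `backbone` structures.
#' @export
make_noisy_homologs <- function(bb, n, sigma, seed = 1, prefix = "homolog") {
  tor <- backbone_torsions(bb)
  out <- list()
  for (i in seq_len(n)) {
    set.seed(seed + i)
    nt <- tor
    nt$phi <- wrap_angle(ifelse(is.na(nt$phi), NA, nt$phi + stats::rnorm(nrow(nt), 0, sigma)))
    nt$psi <- wrap_angle(ifelse(is.na(nt$psi), NA, nt$psi + stats::rnorm(nrow(nt), 0, sigma)))
    nt$omega <- ifelse(is.na(nt$omega), NA, nt$omega)
    out[[sprintf("%s%02d", prefix, i)]] <-
      backbone_from_torsions(tibble::tibble(phi = nt$phi, psi = nt$psi,
                                            omega = nt$omega, aa = nt$aa))
  }
  out
}

#' Generate decoy fragment-source structures
#'
#' Emits single-chain decoys with diverse (Ramachandran-drawn) torsions
#' plus, optionally, a copy of each supplied native under a distinct
#' `native_<id>` source id, enabling both the homolog-excluded and
#' homolog-present fragment-picking regimes.
#'
#' @param n_structures Number of decoy chains.
#' @param length Residues per decoy.
#' @param seed Master seed.
#' @param natives Optional named list of native `backbone` structures to
#'   include.
#' @return A named list of `backbone` structures keyed by source id.
#' @export
make_fragment_sources <- function(n_structures, length = 30, seed = 1,
                                  natives = NULL) {
  out <- list()
  for (i in seq_len(n_structures)) {
    set.seed(seed + i)
    draws <- sample_rama(length, "general")
    # decoys carry their own random reduced-alphabet sequences so they are
    # not trivial sequence matches for fixture queries
    tor <- tibble::tibble(phi = draws$phi, psi = draws$psi, omega = 180,
                          aa = sample(FIXTURE_ALPHABET, length, replace = TRUE))
    out[[sprintf("decoy%02d", i)]] <- backbone_from_torsions(tor)
  }
  if (!is.null(natives)) {
    for (nm in names(natives)) out[[paste0("native_", nm)]] <- natives[[nm]]
  }
  out
}
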