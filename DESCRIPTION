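Package: loopforge
Title: Robotics-Inspired Kinematic Loop Modeling and Backbone Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Backbone loop modeling with analytic kinematic closure (KIC) and its
    fragment-coupled (FKIC) and loophash-coupled (LHKIC) variants. Provides backbone
    structure input/output in PDB format, internal-coordinate chain building, an
    analytic inverse-kinematics solver for pivot torsions, fragment library
    construction with the chord fragment-distance statistic, a 6D rigid-transform
    loophash database, a simplified backbone energy with harmonic coordinate
    restraints, Monte Carlo sampling protocols, ensemble evaluation metrics
    (lowest-energy-model RMSD and sub-angstrom fractions), and a desk-scale
    pull-into-place (PIP) design loop with Pareto-front candidate selection.
    All functionality is exercised on programmatically generated mini-protein
    fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
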