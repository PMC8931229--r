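---
title: "Kinematic loop modeling with loopforge: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinematic loop modeling with loopforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopforge)
```

## The modeling problem

Local backbone segments without regular secondary structure — loops — are
both the hardest part of protein structure prediction and the part that
must be reshaped when a functional group has to be repositioned in design.
loopforge models a segment of an otherwise fixed protein backbone in
torsion space: all bond lengths and angles are held at idealised values
(`ideal_geometry()`), the residues flanking the segment are immovable
anchors, and a conformation of the segment is a list of `(phi, psi, omega)`
triplets realised by forward kinematics (sequential NeRF atom placement).

The difficulty is closure: after changing any torsion mid-segment, the
chain no longer reconnects to the downstream anchor. The package's core is
an analytic inverse-kinematics solver for this closure problem, used inside
three Monte Carlo samplers that differ only in where the non-closure
degrees of freedom come from.

## Kinematic closure (KIC)

A KIC move designates three C-alpha atoms of the N-residue segment as
*pivots* — here always the first and last segment residues plus one random
interior residue — leaving N − 3 nonpivot C-alphas. Nonpivot torsions are
set by a sampler; the six pivot `phi/psi` torsions are then *solved* so the
chain reconnects exactly.

The solver (`solve_closure()`) uses the classic triangle reduction. Once
nonpivot torsions are fixed, the two chain pieces between consecutive
pivots are rigid bodies, so the three pivot C-alphas form a triangle with
known side lengths; the middle pivot lies on the circle cut by two spheres
around the fixed end pivots, parameterised by an angle `tau`. Each rigid
piece keeps one spin angle about its pivot-to-pivot axis; the N–CA–C bond
angle constraint at the two end pivots eliminates both spins in closed form
(two branches each, the roots of `A cos s + B sin s = C`). What remains is
a single smooth residual in `tau` — the deviation of the N–CA–C angle at
the middle pivot — with up to four branches. The solver scans `tau` densely
(default 360 points), brackets every sign change, refines brackets by
batched subdivision to ~1e-8 rad, and handles two delicate cases:

* **validity boundaries** — where a spin discriminant changes sign between
  grid points, the boundary is located by bisection and the edge interval
  checked for a hidden root;
* **grazing closures** — configurations where the middle-pivot angle
  constraint cannot be met exactly for any `tau` but comes so close that a
  short damped Gauss–Newton polish of the six pivot torsions brings the
  chain-end mismatch below the closure tolerance (1e-4 Å). These are
  genuine solutions under the stated tolerance and are kept.

Every returned solution is verified by rebuilding the segment forward and
measuring the maximum deviation of the three downstream anchor atoms
(`closure_residual`); nonpivot torsions are carried through bit-exactly.
Completeness is certified empirically, not by construction: the test suite
compares the solver against an independent multistart Levenberg–Marquardt
enumeration of closure-residual zeros over the six pivot torsions on dozens
of random problems (a 6-D brute-force grid at the resolution needed for
completeness is computationally out of reach, so dense multistart
least-squares is used as the independent oracle).

A subtlety worth recording: the torsion `phi` of the residue *after* the
segment involves the segment's terminal carbonyl carbon yet belongs to the
fixed region. The modeling protocol preserves its value while the segment
is resampled (the chain is conceptually broken inside the segment, not at
the downstream junction), and closure pins the C-side anchor through it.
loopforge captures this junction torsion when a segment is initialised for
sampling and stores it with the structure, because the extended-start
structure itself no longer carries the information in its coordinates.

## Sampling moves

* **KIC (baseline)** — nonpivot `phi/psi` drawn independently from
  residue-class Ramachandran tables, `omega` trans.
* **FKIC** — nonpivot torsions come from sequence-picked fragments. A
  fragment library (`build_fragment_library()`) holds, for every alignment
  frame along the query and every size in {1, 3, 9}, up to 200 source
  windows ranked by a BLOSUM62 similarity sum (a desk-scale stand-in for
  profile-based fragment picking). A move draws size class, frame and
  fragment uniformly, applies the fragment's `phi/psi/omega` to the
  overlapped positions (frames may overlap the segment only partially, so
  9-mers remain useful on short loops when the query carries flanking
  context; see `segment_query()`), and closes with KIC.
* **LHKIC** — nonpivot torsions (and optionally the sequence) come from a
  *loophash* database (`build_loophash_db()`): loop conformations keyed by
  the bucketed 6D rigid transform between their bounding residues
  (translation bins 1 Å, intrinsic z-y-x Euler rotation bins 15°,
  Chebyshev query radius 1 bucket). The move queries the database with the
  transform across the segment's gap and applies a random returned loop.
* **CCD (baseline)** — fragment insertion closed by cyclic coordinate
  descent, which adjusts *every* segment torsion while shrinking the break;
  KIC instead confines closure changes to the three pivots, preserving the
  inserted fragment's conformational information.

Moves are composed into independent Metropolis trajectories
(`run_monte_carlo()`): geometric temperature anneal (default 2.0 → 0.6 over
10 × 20 cycles; the staged multi-resolution protocol of production
packages is deliberately not reproduced), move failures count as
rejections, and the best-energy *closed* structure of each trajectory is
recorded as one model. Trajectory `i` seeds its generator with
`seed + i`, making runs bit-reproducible. Surviving closure solutions are
screened against the Ramachandran tables at the pivots (floor 1e-4 of the
class peak) and the survivor is chosen uniformly at random by default; the
`"lowest-energy"` option scores each candidate and takes the best, which
we recommend (and use in the acceptance runs) because with the simplified
energy below the uniform pick adds considerable noise on short segments.

## The simplified backbone energy

The all-atom energy functions of production modeling suites are explicitly
out of scope. loopforge ranks conformations with a documented three-term
surrogate (`score_backbone()`):

* `rama` — per-residue `-log` density from the package's Ramachandran
  tables (weight 1);
* `clash` — soft-sphere overlap over backbone atom pairs at residue
  separation ≥ 2, `((r0 - d)/r0)^2`, `r0` = 3.4 Å for CA–CA and 3.0 Å
  otherwise (weight 10);
* `restraint` — harmonic coordinate restraints `k d^2` (weight 1, default
  `k` = 1 energy/Å², the "gently pulled" regime; the functional form
  beyond "harmonic" and the spring constants are package defaults, not
  literature values).

This energy suffices to rank closed, clash-free, Ramachandran-plausible
loops. It does **not** capture hydrogen bonding, solvation or side-chain
packing, so no magnitude comparison with any published score is meaningful,
and benchmark numbers obtained with it are directional analogues, not
reproductions, of published results.

The Ramachandran tables themselves are synthetic: 10°-binned grids
generated from a parametric mixture of the canonical basins (alpha, beta,
polyproline-II, left-handed alpha) for four residue classes (general,
glycine, proline, preproline), normalised to class peak 1, with bins below
1e-6 of total mass set to exact zero — these zeros define the disallowed
region used for rejection. `write_rama_table()`/`read_rama_table()` expose
them as plain text.

## Evaluation metrics

`backbone_rmsd()` implements the benchmark metric: superpose the model on
the reference using only non-segment backbone atoms, then compute the RMSD
over the segment's N, CA, C and O atoms (all four atoms everywhere; an
`atoms` argument exposes N/CA/C-only variants). Per case,
`evaluate_ensemble()` reports the RMSD of the single lowest-energy model
(ties to the lower model index) and the fraction of models below 1 Å
("sub-ångstrom"); `dataset_summary()` takes medians across cases. All
generated models are counted in the fraction — no post-hoc filtering.
`case_fragment_distance()` aggregates fragment quality as the mean over
3-mer frames of the per-frame minimum mean chord distance
`<D> = mean(D²(phi)/2 + D²(psi)/2)`, `D²(a, b) = 2 - 2 cos(a - b)`, the
aggregation rule being a package choice where only the per-pair formula is
standard.

## The pull-into-place (PIP) design loop

`run_pip()` composes the desk-scale design protocol: (1) restrained LHKIC
sampling per segment-length variant (deltas 0 … −6, deletions taken from
the downstream end of the segment, candidates never compared across
deltas), filtered to the best restraint-satisfiers per delta
(`restraint_satisfaction()` = maximum distance of any restrained atom to
its ideal position); (2) sequence adoption from the loophash entries
applied during sampling — rotamer-based sequence design is out of scope, so
fragment-sequence adoption is the package's entire design step; (3) exact
Pareto selection (`pareto_select()`, minimising total energy, restraint
satisfaction, clash and rama; fronts above the size cap are thinned by
NSGA-style crowding distance) or Boltzmann-weighted selection
(`boltzmann_select()`); and (4) unrestrained FKIC re-prediction with the
score-gap analysis: models below 1 Å restraint satisfaction are "correctly
placed", above 2 Å "incorrectly placed", the 1–2 Å band is excluded, and
the gap is the minimum energy of the incorrect class minus that of the
correct class. Candidates whose every model is satisfied rank first;
candidates with no satisfied model are flagged failures.

## Synthetic fixtures and what passing tests mean

Every test input is generated programmatically (`make_fixture()`,
`make_benchmark_set()`, `make_fragment_sources()`,
`make_noisy_homologs()`): flank–loop–flank mini-proteins built by forward
kinematics (so loops are closed and geometry is exactly ideal), loop
torsions drawn from the general Ramachandran class and redrawn until
clash-free, sequences taken from a fixed aperiodic pattern over an
8-letter reduced alphabet so fragment picking has an unambiguous sequence
signal. Two-segment cases place two loops around a short helical turn and
are redrawn until at least one inter-segment CA pair sits within 8 Å.
Fragment sources come in three regimes: random-torsion decoys, exact
native copies under distinct ids (for homolog inclusion/exclusion
experiments), and noisy homolog families with controlled torsion noise —
the degradation dial for the fragment-quality correlation experiment.

These fixtures emulate the *shapes* of real benchmark sets, not their
content. Real data differ in ways the fixtures deliberately ignore:
non-ideal bond geometry, side chains and their packing, crystallographic
noise, genuine evolutionary homology, and an energy landscape far richer
than the three-term surrogate. Passing tests therefore demonstrate the
correctness of the kinematics, the samplers, the metrics and the pipeline
logic — they do not certify prediction accuracy on real proteins, and the
published benchmark magnitudes are not reproducible in this setting.

Problem sizes in the shipped test suite are chosen for a laptop-scale run:
6-residue loops, 8–100 models per ensemble, 10–50 moves per trajectory,
50-problem solver-completeness sweeps, ten-case benchmark sets. Each can
be scaled up through the corresponding configuration objects.

## Numerical choices and degenerate inputs

* Closure tolerance 1e-4 Å; solver scan 360 points; bracket refinement to
  ~1e-8 rad; solutions deduplicated at 0.01° in pivot-torsion space;
  solution count is bounded by 16 in all observed instances, as the
  triangle reduction predicts.
* Unreachable anchors (triangle inequality violated) return an empty
  solution set — distinct from solver failure, which raises an error.
* Torsions at chain termini are `NA` (flagged, never invented); segment
  specs touching a terminus are rejected where closure needs both anchors.
* Chain breaks are detected as peptide C–N distances outside
  1.33 ± 0.25 Å and are reported, never silently bridged.
* Angles are wrapped to `(-180, 180]`; the Euler parameterisation used for
  loophash keys bins `beta` without wrap (its range is `[-90, 90]`) and
  wraps `alpha`/`gamma`.
* `kabsch_superpose()` handles collinear point sets (the SVD sign
  correction keeps the rotation proper); fewer than three points is an
  error.

## Known limitations

Backbone only — no side chains, no hetero groups, no mmCIF, insertion
codes rejected. The energy is a surrogate; ensemble energies are only
comparable within a run of this package. The loophash bucketing follows
the package's own documented scheme and databases are not interchangeable
with any external tool's. CCD is provided as a baseline and can stall in
local minima of the break distance (its contract is monotone improvement,
not guaranteed closure). Homology modeling, multi-chain docking and
crystallographic refinement are out of scope.
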