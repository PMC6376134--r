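---
title: "Methods: interface contacts, epitope ranking and coarse-grained unbinding forces"
author: "abforce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface contacts, epitope ranking and coarse-grained unbinding forces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(abforce)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter, what the synthetic generators do and
do not emulate, and the choices made where the design was genuinely open.
Every number quoted here is either a model parameter or something the test
suite and `scripts/acceptance.R` compute themselves.

# The analysis in one paragraph

An antigen–antibody complex — the motivating system is the MOG external
domain bound by an anti-MOG Fab, the canonical target in demyelinating
autoimmune disease — is characterised in five linked stages. Geometric
contact detection counts interface hydrogen bonds and salt bridges per
trajectory frame; the per-residue bond occupancy ranks the antigen's
*anchor residues* and attributes bonds to the six CDR loops. Interval
arithmetic maps the ranked residues onto encephalitogenic peptide windows
(1–22, 35–55, 92–106 in MOG numbering). Kabsch-superposed RMSD series
quantify conformational fluctuation of molecules and sub-regions.
Molecular-mechanics cross energies (Coulomb + Lennard-Jones) decompose the
interface interaction. Finally a coarse-grained constant-velocity pulling
simulator measures rupture forces of the full interface versus the
peptide-window contact subset, and the resulting distributions are compared
with AFM-style adhesion forces extracted from retract curves.

# Contact criteria

A hydrogen bond requires d(D,A) < 3.5 Å **and** an H–D–A angle < 60°; a
salt bridge requires an acidic-residue oxygen within 3.2 Å of a
basic-residue nitrogen. Three decisions here were open:

* **Angle convention.** The angle is measured *at the donor*, between the
  D→H and D→A directions. This is the geometric-cone convention of the
  VMD-style counting protocols used in antibody MD analyses, not the more
  common D–H–A (at the hydrogen, ≥ 120°) convention. The default follows
  the cone rule; `contactCriteria(angle_mode = "dha")` provides the
  conventional rule for cross-checks.
* **Strictness.** Both thresholds are strict (`<`). The synthetic
  generator plants contacts strictly inside the criteria, so boundary
  behaviour never decides a planted count; the test suite probes the
  distance boundary at ±1e-6 Å but deliberately not the *exact* 60° angle,
  where `acos` round-off makes equality meaningless.
* **Protonation.** Histidine is treated as basic (ND1 and NE2 listed, +0.5
  each) because no protonation protocol is assumed; the chemistry tables
  are a versioned YAML file (`inst/extdata/chemistry.yaml`) and can be
  overridden per call. One YAML subtlety is recorded in the file itself:
  the backbone amide key must be written `"N"` quoted, since a bare `N` is
  YAML 1.1 for `false`.

Counting is occupancy-weighted throughout: each (D, H, A) triple in each
frame counts once, so a residue pair may contribute several simultaneous
bonds, and the anchor ranking orders residues by total frame-bond count
with ties broken by ascending residue number. Author (file) residue
numbering is used everywhere; nothing is renumbered.

# Synthetic data: what it emulates, what it does not

`makeComplex()` builds a lattice complex: filler residues carry a minimal
backbone (N–H, CA, O), planted contact residues carry exactly the atoms
the contact needs (SER OG–HG donating to ASN OD1; LYS NZ facing ASP OD1
with its hydrogens turned 120° off-axis so a bridge never doubles as a
hydrogen bond), and a sparse water shell sits 4–8 Å off the interface with
half the waters hydrogen-bonded to backbone carbonyls so protein–water
counting is exercised. The default spec is the package's study condition:
a 110-residue antigen, two 60-residue antibody chains, 13 planted
interface hydrogen bonds at the anchor positions
108, 1, 104, 103, 53, 33, 102, 106, 107, 52, 4, 105, 40 (ranked order),
seven of them to CDR partners so the occupancy-weighted CDR share of
interface bonds sits near 60%, plus 3 salt bridges and 40 waters.

`makeTrajectory()` adds i.i.d. Gaussian positional noise (default σ =
0.1 Å per coordinate) and resolves each planted contact per frame by a
Bernoulli draw: kept contacts are placed exactly at their planted distance
along the (noisy) contact axis, broken ones exactly at 1.2× the criterion
threshold, so the detected state is unambiguous and per-frame counts are
exactly binomial. The default pipeline persistence decreases from 0.95 to
0.5 along the planted ranking, which is what makes the ranking
recoverable. Drift, when requested, is a half-sine displacement of a
selected region — a deformation stand-in, not dynamics.

What the generator does **not** emulate: real interface geometry, solvent
physics, and in particular the inverse coupling of protein–water hydrogen
bonds and salt bridges seen in solvated simulations (that anticorrelation
is attributed to solvation effects, which a noise model cannot produce, so
it is not planted). Passing tests therefore certify the *measurement
machinery* — detection, counting, ranking, superposition, energetics,
extraction — not any claim about real antibody energetics.

All generators are pure functions of (spec, seed). One master seed expands
into per-stage sub-streams by the splitting rule
`(seed · 1000003 + offset) mod (2³¹ − 1)`, so pipeline stages are
independently reproducible; the pipeline determinism test asserts
byte-identical reports for identical (config, seed).

# RMSD

`kabschSuperpose()` is the SVD construction with the determinant sign
corrected, so reflections are never returned; degenerate inputs (fewer
than 3 points, or collinear) are flagged rather than rejected. RMSD series
default to Cα atoms superposed on the same selection against frame 1 —
the fit group and atom subset of published RMSD analyses are usually
unstated, so both are explicit arguments (`mode = "all"`,
`superpose = FALSE`). Values are computed in Å; exports carry Å and nm.
Under pure positional noise the expected all-atom RMSD is σ√3, which the
suite checks at σ = 0.1 and 0.2 Å within 5%.

# Interface energetics

The Coulomb term uses 332.06 kcal Å mol⁻¹ e⁻² with a relative permittivity
argument (default 1) and the Lennard-Jones term Lorentz–Berthelot
combining, both with plain 12 Å cutoff truncation — the inputs are small
static synthetic frames, not periodic solvated systems, so no Ewald
summation. Charges are unit charges split over titratable sites (declared,
not fitted), ε = 0.1 kcal mol⁻¹ and σ = 3.5 Å generically for heavy atoms.
This module corresponds to the gas-phase ΔE_elec / ΔE_vdW rows of an
MM/PBSA-style decomposition only; Poisson–Boltzmann and surface-area
solvation and entropy terms are deliberately not implemented, so a binding
free energy is *not* a package output. The sampling arithmetic is exact:
a window of length T sampled every Δt yields T/Δt values (15 ns at 10 ps
→ 1,500), with non-divisible tails flagged.

# The pulling model

The simulator is an overdamped (Brownian) bead-spring analog of a
constant-velocity SMD protocol, not all-atom dynamics; absolute pN values
are a property of the model, and only protocol arithmetic, curve
phenomenology and orderings (subset < full, monotonicity in bond count,
stiffness and velocity) are meaningful.

* **Protocol parameters** follow the published setup and are the
  constructor defaults: spring constant k = 2.15 kcal mol⁻¹ Å⁻², pulling
  velocity v = 0.025 Å ps⁻¹ (= 0.00005 Å per 2 fs step), 3 ns duration,
  20 replicates, 310 K, with fixed anchor residues on the antibody and one
  pulled antigen residue.
* **Geometry.** `buildPullingSystem()` lays beads out in schematic pulling
  coordinates (the standard cartoon of an SMD setup): each contact pair on
  the pulling axis at its Cα–Cα distance, pairs stacked 2 Å apart
  transversely, the pulled bead 20 Å behind the antigen side, anchors
  behind the antibody side. Unbreakable scaffold springs (total stiffness
  25 kcal mol⁻¹ Å⁻² per side, shared over the arms on the pulled side) tie
  contact beads to the hub and partners to anchors, so the breakable
  interface bonds load cooperatively along the pulling direction — the
  property that makes the full 13-bond interface rupture at higher force
  than the 5-bond peptide subset.
* **Bonds** are harmonic up to a break extension, then permanently off
  (defaults 6 kcal mol⁻¹ Å⁻² and 1.6 Å, i.e. a ~12.5 k_BT well at 310 K —
  deep enough that bonds do not evaporate thermally on the simulated
  timescale, shallow enough that rupture completes inside 3 ns). A Morse
  potential was rejected: the hard break keeps the quasi-static limit
  analytic (F* = k·Δx_break, verified within 5%).
* **Confinement.** Mobile beads feel a weak harmonic restraint
  (2 kcal mol⁻¹ Å⁻²) about their initial positions acting only
  perpendicular to the pulling direction — a crowding surrogate for the
  surrounding protein matrix. Without it the planar schematic leaves the
  out-of-plane coordinate diffusive and bonds break by transverse wander
  at trivial force; because the restraint is transverse-only, the
  analytic axial limits (drag plateau γ·v at T = 0, quasi-static single
  bond) are untouched.
* **Integration.** Euler–Maruyama with γ = 1 kcal mol⁻¹ ps Å⁻². The
  protocol timestep default is 0.002 ps; the pipeline overrides it to
  0.01 ps, which is stable for the stiffest spring in the default build
  (k·dt/γ = 0.27) and five times cheaper. Runs stop 50 ps after
  separation (all breakable bonds off and the pulled bead 10 Å past its
  bound position); a run that never separates is an unruptured flag, not
  an error. Thermal noise uses R's RNG, one sub-stream per replicate, so
  replicate sets are bit-reproducible under a seed.
* **Rupture definition.** The rupture force is the maximum recorded spring
  force before separation (peak-before-separation); the curve-level
  extractor reads the same peak from the raw trace and uses a median
  filter only to locate the trailing plateau, because filtering a sharp
  apex would clip it. Phases are labelled maintenance (up to the peak),
  detachment (peak to plateau onset), separation (the plateau).

# Force spectra and the distribution comparison

AFM retract curves use the force-spectroscopy convention (nm abscissa, pN
ordinate). The synthetic retract is the physical shape: the contact line
descends at `contact_slope` through zero into the adhesion branch,
reaching −Fad exactly at the pull-off position before snapping to the
baseline. That makes the minimum a sharp corner, so the adhesion estimate
(trailing-window baseline median minus trace minimum) is recovered exactly
without noise and without bias under noise — a shallow well would have
made the noisy minimum estimator biased by several pN. Boxplots follow
Tukey's convention (1.5 × IQR whiskers), the published convention being
unstated. The comparison reports, for every ordered pair of groups, the
containment fraction of one group inside the other's min–max range and
whether its median falls inside the other's interquartile box, plus
pairwise rank tests. One quantitative caution is recorded in the tests:
with simulated forces N(780, 128²) against 30 adhesion values drawn from
N(765, 80²), the *expected* containment is about 0.83, because the range
of 30 draws spans only ±2.2 SD — claims of ≥ 90% containment depend on the
luck of the measured range.

# Pipeline, problem sizes and interface

`runPipeline()` chains every stage deterministically and emits a
machine-readable summary (plus CSV/JSON artifacts when an output directory
is given): ranking, CDR fraction, window report, count series with block
averages, RMSD means, energy decomposition, rupture statistics for the
full and peptide-window systems, AFM statistics, the distribution
comparison and the force fraction. The default problem sizes — a
1,001-atom complex, 200 frames, 20 pulling replicates per system, 30 AFM
curves — were chosen so the full pipeline runs in well under a minute on
one core while leaving every statistical check comfortably powered; the
test suite uses smaller variants of the same conditions. The package's
interface is its functions, this document and the YAML config read by
`readPipelineConfig()`; no shell entry point is shipped, since every
pipeline invocation is a one-liner in R and the acceptance script shows
the canonical call.

# Known limitations

* The interface is synthetic; no claim about real 1PKQ-like geometry or
  energetics follows from green tests.
* Solvation physics is absent everywhere: water is decorative in the
  generator, and the energy module stops at the gas-phase MM terms.
* The pulling model's absolute forces scale with bond stiffness and count
  by construction; only comparisons within the model are meaningful.
* Contact detection is O(donors × acceptors) per frame — fine at these
  sizes; a cell-list accelerator would be needed for solvated systems,
  and would be required to match the plain detector bit-for-bit.
* mmCIF, crystallographic assemblies, occupancy/B-factor modelling and
  structure refinement (missing residues, protonation engines) are out of
  scope; PDB fixed-width I/O with an explicit chain→molecule map is the
  only structure format.
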