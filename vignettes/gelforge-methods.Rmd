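---
title: "Methods: coarse-grained design and statistics of cyclodextrin-functionalized PVA hydrogels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained design and statistics of cyclodextrin-functionalized PVA hydrogels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gelforge is a desk-scale re-implementation of the rational-design workflow
behind γ-cyclodextrin-functionalized, succinic-acid-crosslinked polyvinyl
alcohol (PVA) hydrogels used as sustained-release platforms for hydrophobic
drugs such as prednisone. The workflow has four computational stages —
host–guest orientation screening, crosslinked-network construction,
structural observables over coordinate frames, and the factorial statistics
of swelling and release — plus a synthetic-data stage that generates every
input class with known ground truth. This vignette records the models, the
conventions adopted where the original procedures are underspecified, and
the limits of what the test suite demonstrates.

## Molecular model and builders

Molecules are ordered atom tables (element, Cartesian position in Å,
partial charge in e, van der Waals radius in Å, free-text role tag) plus a
bond list. Structures are built from idealized geometry — C–C 1.54 Å,
C–O 1.43 Å, C–H 1.09 Å, O–H 0.96 Å, tetrahedral angles — rather than
quantum-optimized coordinates: every downstream operation here is geometric
or classical-energetic, and standard bond lengths are sufficient for those
contracts. PVA chains are extended zig-zags of –CH~2~–CH(OH)– units with
H-capped ends and atactic (seeded random) hydroxyl placement; tacticity and
end-group treatment are not specified by the source synthesis, so atactic
placement with H caps is the package's choice. The γ-cyclodextrin builder
produces a heavy-atom ring with tagged glycosidic, secondary-face and
primary-face oxygens; its geometry is schematic (rim radius 5.9 Å for eight
units) but its cavity frame and anchoring points are exact by construction,
and the true molecular formula (C~48~H~80~O~40~) rides along as metadata so
mass bookkeeping stays correct. Molar masses use the 2021 IUPAC abridged
standard atomic weights; the table is replaceable per call.

XYZ (1 µÅ precision) and PDB (fixed columns, 1 mÅ) readers/writers are
implemented in-package so both report malformed records with their line
number and so the round-trip contract lives in one place; the PDB writer is
cross-checked against an independent reader in the test suite.

## Energy model

Screening needs only a map from a rigid molecular system to a total energy.
The bundled model sums pairwise 12-6 Lennard-Jones terms under
Lorentz–Berthelot mixing plus Coulomb terms with
k~e~ = 332.0636 kcal Å mol⁻¹ e⁻², relative permittivity 1 by default.
Pair distances below 0.5 Å are clamped to the value at the cap so random
rigid sampling never produces unbounded energies; the clamp applies
identically in whole-system and fragment evaluations, so the supermolecular
identity below is exact. Per-element σ/ε defaults are generic
(C 3.4 Å/0.086 kcal mol⁻¹, O 3.0/0.17, H 2.5/0.03, with a wildcard
fallback) and replaceable. Absolute energies from this model are **not**
comparable to semi-empirical quantum values; the pipeline's logic — the
supermolecular difference, ensemble statistics, lowest-k selection,
ranking — is what the package reproduces, and the test suite checks those
contracts on synthetic systems with known ground truth, not published
energy magnitudes.

The supermolecular interaction energy is ΔE = E(complex) − E(host) −
E(guest) at fixed internal geometries, computed from three model
evaluations. For rigid fragments this equals the direct inter-fragment pair
sum; the suite verifies the identity to 10⁻⁹ kcal mol⁻¹ over a thousand
random poses, and rigid-motion invariance to machine precision.

## Orientation screening

How the original 100 000 guest orientations were drawn is not stated
anywhere in the source procedure, so the package samples rotations
uniformly on SO(3) (subgroup-algorithm quaternions) and translations
uniformly over a spherical shell around the host centroid (default outer
radius: host radius + guest radius + 5 Å). A note on the uniform-rotation
check in the tests: under Haar measure the *expected trace* of a rotation
matrix is 0 (E[cos θ] = −1/2 under the (1 − cos θ)/π angle density), and
that is what the Monte-Carlo test asserts.

The lowest-k subset (k = 100 by convention) is selected by energy with ties
broken by pose index, so re-runs are stable. Inclusion classification is a
declared geometric convention, because "inclusion" has no quantitative
definition in the source: a pose is an inclusion when any guest atom
projects inside the cavity cylinder (radius = rim radius, axial extent
±4 Å around the cavity center), and the label is A when the end-A marker
centroid sits deeper along the secondary→primary axis than the end-B
centroid, B otherwise. The cavity frame of a built cyclodextrin is the
centroid/principal-axis/mean-radius of its glycosidic oxygens, oriented so
the secondary rim has negative depth.

## Network construction

The default configuration is the modelled study system: 56 chains × 35
monomers (1960 monomers) in a 90 × 80 × 100 Å orthorhombic box, ≥ 5 Å
inter-chain separation, crosslink formation cutoff 10 Å, and a 10:2
PVA:SA stoichiometry giving a target of `round(1960 × 2/10)` = 392
succinate bridges. Two –OH groups on distinct chains within the cutoff are
drawn uniformly at random, esterified with an idealized succinate diester
(hydroxyl hydrogens removed, diester fragment bonded in), and the
neighborhood within 6 Å of the new bridge is relaxed by steepest descent.
The loop repeats until the target or until no eligible pair remains, which
raises a structured *shortfall* error carrying the partial model and the
achieved count — an error rather than silent truncation, because the
stoichiometric target is treated as exact.

Packing uses seeded rejection sampling with random rigid placement. For
chains short relative to the box, proposals are isotropic. A 35-monomer
extended chain is ~88.5 Å long — nearly the box edge — and isotropically
oriented rods of that length jam far below full occupancy (random
sequential adsorption saturates early once placed rods criss-cross the
box). Optimizing packers resolve this by construction; the rejection
sampler resolves it by proposal design: when the chain span exceeds 80% of
the smallest box edge, proposals align the chain's principal axis with the
most spacious feasible box axis from the first attempt (random sign and
spin about the axis), and translations alternate between uniform draws and
jittered lattice slots in the perpendicular plane whose pitch is the
largest chain footprint plus the separation distance. Every proposal is
still validated against the exact atom–atom separation contract, and the
whole procedure is deterministic given the seed. The default full build
packs in seconds and completes 392/392 bridges in about three minutes on
one CPU.

Local relaxation is plain steepest descent with a backtracking step on the
nonbonded energy (1-2 and 1-3 pairs excluded) plus harmonic restraints
holding bonds at their entry lengths (k = 300 kcal mol⁻¹ Å⁻²). Angle
restraints were considered and omitted: the relax stage only has to
relieve clashes around freshly inserted bridges, its contracts (energy
non-increase, LJ-dimer minimum recovery, termination on gradient norm
< 10⁻³) do not require them, and bond-only restraints keep the gradient
simple. The per-bridge relax budget defaults to 20 steps in the builder —
enough to remove hard clashes; `local_relax()` itself defaults to 200.

Cyclodextrin grafting anchors each CD by one primary-face hydroxyl oxygen
to the carbonyl carbon of a distinct succinate bridge, choosing unclashed
placements pointing away from the gel interior. This is a deliberate
coarse-model convention: a fully diesterified bridge has no free
carboxylate in real chemistry (grafting there actually involves partially
esterified crosslinker), but anchoring to bridges keeps the bookkeeping the
source describes — no extra hydroxyl sites consumed, one ester (one water)
per CD anchor — and the mapping {0, 6, 12, 24} CDs ↔ ≈ {0, 2.5, 5, 10}%
is taken as configuration, not derived, since both are stated without a
formula. Guest placement applies the same rejection scheme at ≥ 10 Å
clearance; the default placement box is a 160 Å cube centered on the gel
(the solvation-box size the modelled systems are re-centered into), because
the build box itself has no point 10 Å clear of a network that spans it.

## Frame observables

Frames are coordinate snapshots with per-atom component tags (gel, water,
guest~i~) and masses; no periodic imaging is applied, so inputs must be
pre-imaged. The observables:

* **RGYR** — mass-weighted radius of gyration about the mass-weighted
  centroid, checked against the brute-force formula to 10⁻¹⁰.
* **SASA** — Shrake–Rupley with a *deterministic Fibonacci spiral* lattice
  (default 960 points, probe 1.4 Å) so results are bit-reproducible.
  Because the lattice is laid in the lab frame, rigid-motion invariance
  holds to the lattice resolution (≈1% at 960 points), not machine
  precision; the analytic single-sphere value is reproduced within 0.5%.
* **Waters in the gel** — waters (by oxygen position) within 3.0 Å of any
  gel atom, plus all waters inside the gel envelope. "Inside" is a declared
  convention: the set of 2 Å grid cells not reached by a 6-connected flood
  fill from the bounding-box boundary. It is simple, testable on hollow
  constructions, and resolution-configurable.
* **Guest capture** — a guest is captured when any of its atoms is within
  4.5 Å of any gel atom; on trajectories a persistence parameter (default
  1) requires the contact to hold over that many consecutive frames, since
  "stably captured" has no stated quantitative definition.
* **Hydrogen bonds** — geometric criterion D···A ≤ 3.5 Å and D–H···A
  ≥ 150°, donor and acceptor in different components; both thresholds are
  configurable because the source states none.

Series evaluation is per-frame in frame order; block averaging uses
contiguous equal blocks (remainder to the last), reporting the overall mean
and the SE of block means (NA for a single block).

## Release statistics

Factors are coded onto [−1, 1] by the min–max transform
coded = 2(x − min)/(max − min) − 1, with an exact inverse and no
extrapolation outside the design range. Effect screening is OLS on the
coded regressors with an intercept; the standardized effect is
|coefficient/SE|, Pareto-ordered, with significance against the two-sided
critical t at 95% confidence. Reduced-model fits refit OLS on exactly the
included terms; R² is reported in percent (matching the conventions of the
published equations this stage mirrors), and a constant response defines
R² = 0. OLS itself is delegated to `stats::lm()`; the coding,
standardized-effect and percent conventions are the package's layer.

Two printed-value caveats are worth recording. First, the packaged 20-row
release design table does **not** reproduce the originally reported
reduced-model regression (intercept 69.95, composition coefficient 30.66,
interaction 5.53, R² 64.77%) under ordinary least squares: the reduced fit
on the printed rows gives 69.00/33.76/3.37 with R² 78.05%, the full model
differs only marginally, and cell-mean, subset and quadratic variants were
all checked. Second, on the same printed rows the composition×time
interaction is not statistically significant (|t| ≈ 0.7), although the
original Pareto analysis reported it as significant. Both discrepancies
indicate the original statistical software ran on data or weighting not
printed in the 20-row table; the package therefore computes and reports
both the reduced and the full fits, asserts only what the printed data
yield (composition strongly significant, time not), and treats the printed
coefficients as documentation, not as recoverable targets. The swelling
regression of the same study design is exercised purely through synthetic
parameter recovery, because its underlying table is in an appendix not
available here.

Swelling index uses the swollen-mass denominator exactly as originally
printed, (M~h~ − M~x~)/M~h~ × 100 — note this differs from the common
xerogel-denominator convention. Drug content is the positive mass
difference loaded − unloaded; the printed operand order would be negative
and is taken as a typographical artifact, flagged rather than asserted.
Cumulative release applies the aliquot mass balance by default
(mass~i~ = c~i~·V + Σ~j<i~ c~j~·v~j~ for withdrawn-and-replaced aliquots;
the original protocol does not state whether it corrected, so the switch is
exposed); with the correction on, physically monotone concentration
profiles give monotone release. Release-profile summaries interpolate the
burst percentage at the burst window (default 2 h) and fit the zero-order
slope by OLS over the late window.

## Synthetic data

Each generator emits its ground truth and verifies it after construction by
brute-force distance checks, independent of the counters under test: a
two-rim ring host with an open, attractive cavity; rod guests with disjoint
end markers; hollow-shell gel frames with specified numbers of waters
inside/outside the envelope and guests in/out of capture contact (jitter is
re-drawn up to 100 times and rejected if it breaks a category); factorial
tables y = b₀ + b₁A + b₂B + b₃AB + N(0, σ), including the exact 6-cell,
20-row layout of the packaged release design; and biphasic release curves
with a saturating-exponential burst joined continuously to a linear
zero-order phase. Passing tests on these fixtures demonstrates the
correctness of the counting, screening and regression logic — not the
thermodynamics of real hydrogels: the fixtures have no water structure, no
real drug chemistry, and category margins built in.

## Problem sizes and numerical choices

The test suite runs everything at desk scale, chosen as the smallest sizes
that exercise each contract: screening basins at 20 000 poses against a
~10⁶-point exhaustive translation grid; the crosslink property suite at 10
chains × 10 monomers over 20 seeds plus one full 56 × 35 build; counter
ground truth over 50 seeded frames; factorial recovery over 200 replicates
at σ = 5. Determinism everywhere flows from explicit integer seeds;
stochastic acceptance checks use 3-standard-error bands. Known limitations:
idealized geometry only (no conformational sampling during screening — the
rigid-body design is inherited), no periodic boundaries, no solvent
thermodynamics, schematic cyclodextrin geometry, and energies on an
artifact scale rather than a quantum one.
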