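---
title: "Models and methods behind connexon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind connexon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connexon)
```

# Scope

`connexon` quantifies two things about gap-junction channels (GJCs):
the distribution of protomer conformational states across dodecameric
particles, measured from symmetry-expanded single-particle classification
metadata; and ion permeation, measured from trajectory data.  It is a
metadata- and trajectory-analysis package: it performs no image
processing, no 3D classification, and no force-field molecular dynamics.
Those stages are represented only by their outputs (STAR tables, ion
coordinates, atomic models), which the synthetic generators can emulate
with known ground truth.

# Classification-metadata bookkeeping

## Symmetry expansion and record identity

A D6-symmetric dodecamer has 12 symmetry-related placements of each
particle image: 6 in-plane rotations (0, 60, ..., 300 degrees) for each of
the two hemichannels.  `expandSymmetry` replicates records accordingly,
and `groupByParticle` inverts the mapping.  Three conventions are fixed
here because upstream software does not standardise them:

- **Particle identity** is the `rlnImageName` string, treated as an opaque
  key (no parsing of micrograph paths or stack indices).
- **Ring position** is `round(rot_deg / 60) mod 6` after reducing the
  rotation angle into [0, 360).  The rotation offsets applied during
  expansion are exact multiples of 60 degrees, so rounding only matters
  for hand-edited tables.
- **Hemichannel flip** travels in `rlnAngleTilt` (0 = original copy,
  180 = the copy expanded into the opposite hemichannel) and is read back
  as tilt > 90.

Deduplication before composition counting uses the key *(particle id,
hemichannel, position)*: two records claiming the same physical protomer
slot are redundant regardless of their class labels, and the first one
seen wins.  Particles whose record multiplicity differs from the group
order after deduplication are excluded and reported, never imputed — an
incomplete dodecamer has no well-defined composition.

## States and third conformations

Class-to-state mapping is explicit (`ClassStateMap`); the default is the
eight-class result of the wild-type nanodisc dataset (PLN: classes 1-4
and 7; FN: classes 5, 6, 8).  Classes outside the map become
`UNASSIGNED`.  A third conformation (such as the gate-covering state seen
in other connexins) can be mapped to `OTHER`; binary FN:PLN summaries
refuse tables containing it unless `foldOtherIntoFN = TRUE`, which counts
it on the FN ("not pore-lining") side.  The default refusal is
deliberate: silently dropping a third state would bias both the
composition histogram and the ring statistics.

State fractions are computed **per protomer record**, not per particle.
For complete tables the two weightings coincide; for tables with excluded
incomplete particles they can differ in the third digit, and the
per-record estimate uses strictly more of the data.

## Hetero-junctional selection

The experimental selection of hetero-junctional particles worked at the
level of hemichannel 3D classes.  Working from protomer states instead,
a hemichannel is assigned to the PLN (or FN) group when at least
`threshold` of its six protomers carry that state.  The default
`threshold = 6` (conformationally pure rings) is the conservative
approximation of a hemichannel-level class; lowering it to 5 or 4 admits
mixed rings and is exposed for sensitivity analysis.  Thresholds below 4
are rejected, since a ring could then satisfy both groups.

# Ring-arrangement statistics

## Necklace classes

Arrangements within a hemichannel are compared under **rotation only**
(the cyclic group C6), giving 14 classes for binary states with
composition multiplicities 1, 1, 3, 4, 3, 1, 1 for k = 0..6 PLN
protomers.  Reflections are *not* identified by default: the two faces of
a docked ring are physically distinguishable (one faces the junction, one
the cytoplasm).  `dihedral = TRUE` merges mirror pairs (13 bracelet
classes) for sensitivity analysis.  Canonical representatives are the
lexicographically smallest rotation with F < P; ties cannot occur because
the minimum is taken over the orbit itself.

Under independent placement at PLN probability p, a class of orbit size s
and PLN count k has expected frequency s·p^k(1−p)^(6−k); these sum to 1
over the 14 classes for any p, which the tests verify.

## Goodness of fit and its calibration

The default test is a Pearson chi-square with all classes of expected
count < 5 pooled into one bin.  p defaults to the plug-in estimate from
the same rings, in which case the degrees of freedom are reduced by one
(bins − 2); a fixed-p mode skips the reduction.  An exact multinomial
Monte-Carlo test (default 10,000 replicates, explicit seed) is available
for sparse tables where the chi-square approximation is doubtful.  The
test suite checks calibration, not just arithmetic: over 500 null
datasets of 10,000 rings the rejection rate at the 5% level must stay
within 0.05 ± 0.02.

## Neighbour coupling

`adjacencyCouplingStat` targets weak nearest-neighbour interactions the
global goodness-of-fit can miss: the statistic is the mean number of
cyclically adjacent equal-state pairs per ring (0-6), and the null is
generated by permuting states across positions *within each ring*, which
preserves every ring's composition exactly and destroys only the spatial
arrangement.  The p-value is two-sided Monte-Carlo.  Below 100
permutations the function warns but still computes.

# Permeation statistics

## Crossing definition

No standard definition of a "permeation event" exists for trajectory
post-processing, so the package fixes one: **two-plane hysteresis**.  An
upward event is recorded when an ion last below z_lo first exceeds z_hi
(default gate ±5 Å around the junction midplane z = 0, the declared
coordinate convention).  Ions entering the gate region and retreating are
not counted, which suppresses diffusive recrossing noise; a single-plane
counter would overcount by the number of such excursions.  Periodic-wrap
jumps (|dz| > box_z/2) are unwrapped first, so passage through the
periodic boundary is never mistaken for a gate crossing.  On strongly
drifting trajectories the hysteresis net count agrees with a single-plane
count to within recrossing corrections (tested at 2%).

## Currents, conductance, uncertainty

I = q·e·net/T converts counts to nA; g[pS] = 10^6·I[nA]/V[mV].  The
arithmetic is exact and tested bit-stably: 0.007 nA at 200 mV is 35 pS,
0.024 nA is 120 pS.  The viscosity correction divides conductance by 3.0
by default — the standard three-site water model underestimates viscosity
roughly threefold, inflating diffusion coefficients and currents by the
same factor — and is overridable.  Statistical uncertainty is reported as
the between-block standard error over 20 contiguous time blocks
(`measureCurrent`); zero-field runs must give |I| < 3 SE.

## Profiles and maps

Concentration profiles average ion occupancy in axial bins of a cylinder
and convert with M = occupancy/(N_A·πr²Δz·10⁻²⁷).  The density–flux map
bins time-averaged number density on a cubic grid and assigns each
frame-to-frame displacement (unwrapped, divided by the frame spacing) to
the voxel containing the displacement midpoint; the flux slot stores the
occupancy-weighted mean displacement rate.  Mass conservation (density
integral = mean ion count) is tested to 1%.

# Pore-radius profiling

At each axial sample the profiler maximises, over the in-plane centre,
the clearance min_atoms(|c − x_i| − r_vdw,i): the largest sphere centred
in that plane overlapping no atom.  The optimiser is multi-start
Nelder-Mead (relative tolerance 1e-10, up to 500 iterations) seeded on
the nominal axis and on four points 2 Å off-axis; tests require agreement
with an exhaustive 0.01 Å in-plane grid search within 0.05 Å on all toy
fixtures.  Atoms further than 15 Å from the sample plane are culled;
planes with no atoms in reach are capped at r_max = 20 Å and flagged
rather than reported as an unbounded radius.

Van der Waals radii come from a single documented Bondi-style table
(C 1.70, N 1.55, O 1.52, S 1.80 Å, ...); unknown elements fall back to
the carbon radius with a warning, and the table is replaceable per call.
Published constriction diameters depend on the radius convention of the
software that produced them, so comparisons with deposited models should
allow a few tenths of an Ångström either way.  The profiler follows a
straight axis only — no Monte-Carlo path wandering — which is adequate
for the roughly axisymmetric channels it targets.

# Synthetic generators: what they emulate, and what they do not

## Classification metadata

`simulateMetadata` reproduces the *bookkeeping* of a protomer-focused
classification: one record per symmetry copy, rotation angles on the
60-degree grid, class labels drawn uniformly within each true state.  Its
default PLN fraction of 0.57 is the observed 57/43 protomer split of the
wild-type nanodisc dataset, which the acceptance script simulates at its
full size of 85,080 particles; the companion fractions 0.29 and 0.88 used
in the recovery tests are the ratios observed in the detergent and
BRIL-fusion datasets.  At J = 0
protomers are independent Bernoulli draws.  At J ≠ 0 each ring follows a
6-cycle Ising model sampled by a Gibbs sampler (500 burn-in sweeps, far
beyond the mixing time of a 6-spin ring) whose field is solved by
bisection on the exactly enumerated marginal to 10⁻⁶; `exactRingDistribution`
provides the exact 64-state law, and the sampler must match it within
total-variation 0.01.

What it does **not** emulate: class-assignment errors (every record's
class is consistent with its true state), alignment errors in the
rotation angles, per-micrograph or per-optics-group structure, and
inter-hemichannel coupling (the two rings of a particle are sampled
independently).  Passing tests therefore demonstrate correct bookkeeping
and calibrated statistics under the stated generative model — not
robustness to misclassification, which would require an error model the
experimental data do not constrain.

## Ion trajectories

`simulateIonTrajectory` integrates overdamped Langevin dynamics of
non-interacting ions in a reflective cylinder, periodic along z, with the
constant field E = V/L applied inside the pore segment and optional
Gaussian potential wells emulating attractive (acidic-band-like) regions.
Defaults: D = 0.1 Å²/ps (a sodium-like diffusivity), 300 K, 200 mV.  A
stability guard rejects configurations whose deterministic displacement
per step reaches 0.5 Å.  When the pore spans the whole box (no
reservoirs) and no wells are present, the steady-state density is uniform
and the drift current obeys I = q·c·A·D·qE/kT exactly
(`closedFormCurrent`), the oracle used by the current tests; with
reservoirs or wells the oracle refuses, because the density is then
non-uniform and the constant-field formula no longer holds.

Not emulated: water, ion-ion and ion-protein interactions, a realistic
pore geometry, electrostatic self-consistency.  The generator validates
the *measurement* chain (crossing detection, current conversion,
profiles), not channel physics.

# Problem sizes and numerical choices

The routine test suite uses dataset sizes chosen to make the statistical
assertions sharp while keeping the suite fast to iterate: 50,000
particles for the binomial-composition check, 100 seeds × 800 particles
per fraction for Wilson-coverage (nominal 95%, required ≥ 93/100), 500
null datasets of 10,000 rings for test calibration, 200,000 rings per
setting for sampler-vs-enumeration total variation, 100 ions × 25,000
steps for the current oracle, and a 0.01 Å grid for the pore-profiler
oracle.  The acceptance script mirrors these, with the metadata
simulation at the full 85,080-particle study scale.

Degenerate inputs are rejected loudly rather than coerced: empty tables,
unexpanded tables in composition counting, zero voltage in conductance,
zero cylinder radius, gates wider than the box, all-zero expected counts,
marginals unattainable at the requested coupling.

# Known limitations

- Composition statistics assume the class-state map is correct;
  misclassification propagates directly into p and the histogram.
- The hetero-junctional selection by protomer-count threshold is an
  approximation of hemichannel-level classification; counts are not
  comparable across the two definitions.
- Observed full-state percentages in real datasets can exceed the
  independence prediction (heavy tails); the package exposes both the
  channel-level and ring-level tests and asserts no conclusion either
  way.
- The pore profiler's straight-axis assumption underestimates radii in
  strongly kinked channels.
- Langevin currents validate estimators, not channels: absolute values
  match the generator, nothing more.
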