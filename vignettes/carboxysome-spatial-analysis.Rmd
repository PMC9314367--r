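---
title: "Methods: quantifying Rubisco packing inside α-carboxysomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying Rubisco packing inside α-carboxysomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbxpack)
```

`cbxpack` measures the spatial organization of Rubisco cargo inside
α-carboxysomes from subtomogram-averaging metadata alone. This vignette is
the package's account of its methods: the geometric model, the tunable
parameters and why their defaults are what they are, what the synthetic
generator does and does not emulate, and the numerical and design choices
that were genuinely open.

## Input model and conventions

A particle is a position (Å, tomogram frame), an orientation, and optionally
a template-matching cross-correlation score in [0, 1]. Orientations are
proper rotation matrices mapping particle-frame vectors into the tomogram
frame, parameterized on disk as intrinsic ZYZ Euler angles
(R = R~z~(rot) · R~y~(tilt) · R~z~(psi), degrees) — the dominant convention
in subtomogram-averaging tool chains; any other convention is a fixed
conversion away at the reader. STAR-dialect coordinates are pixel-valued and
require an explicit pixel size (Å/px) — there is deliberately no default,
because a silent Å/pixel mix-up is the classic failure mode of this kind of
plumbing. Internally everything is Å. The coordinate frame is right-handed
and never flipped on read; every statistic the package reports is
handedness-insensitive because twist angles are reported as canonical
unsigned values (below).

Rubisco is a D4 hexadecamer; its fourfold axis is particle-frame +z (the
convention of the deposited maps), so the axis in the tomogram frame is the
third column of the orientation matrix. D4 symmetry has two consequences
that thread through everything:

* the fourfold axis is **undirected** (the twofolds flip it), so all
  axis–axis and axis–displacement angles are folded into [0°, 90°];
* relative rotations between particles are defined only up to the two-sided
  group action, so twist angles are folded modulo 90° and by sign into
  [0°, 45°].

## Canonical twist

For two orientations R₁, R₂ whose fourfold axes pass a collinearity
pre-screen (default 15°, callers tracing strings pass their own parallelism
gate), the relative rotation is taken in the body frame, Q = R₁ᵀR₂, its
swing–twist decomposition about the particle symmetry axis (+z) gives the
raw twist t = 2·atan2(q~z~, q~w~), and the D4 fold maps t to the canonical
representative in [0°, 45°]. Antiparallel axes are first aligned by applying
a twofold group element, which is a no-op under the fold.

An alternative formulation — swing–twist about the mean of the two
sign-aligned axes in the lab frame — agrees exactly when the axes coincide,
but under axis misalignment it is only approximately invariant when an
orientation is right-multiplied by a C4 element (the twist shift is scaled
by the axis projection). The body-frame formulation is *exactly* invariant
under (a) right-multiplication of either argument by any group element,
(b) any global rotation, and (c) argument swap, all of which the test suite
asserts at 10⁻⁹, and which make whole-pipeline invariance checks meaningful
at 10⁻⁶. That exactness is why the body-frame form was chosen.

The reported value is this artifact's definition of "the" inter-particle
twist: a single physical rotation (e.g. 82.7° about the shared axis) has the
whole orbit {±82.7° + 90k} of equivalent descriptions, and the canonical
representative (7.3°) is the minimal non-negative one. Test oracles verify
it against explicit 64-combination enumeration of the two-sided orbit.

## Layer analysis

Compartments are single-linkage connected components at 200 Å within a
tomogram (about two particle diameters; compartments are thousands of Å
apart so the exact value is uncritical over a wide range), with components
smaller than 20 particles left unassigned. Filtering drops scores below 0.1
(the lower edge of the plausible cross-correlation range; planted false
positives score below 0.12) and particles beyond 550 Å of their compartment
center, which removes spurious matches outside the shell.

The compartment **center is the plain mean of member positions** — the
definition used when these distributions were introduced — rather than a
least-squares sphere fit that would be more robust. As a guard, the package
emits a note whenever the mean and the coordinate-wise median differ by more
than 30 Å. (The median replaces an earlier medoid comparison: for a discrete
sample of a hollow shell the medoid necessarily sits on the shell, tens of Å
from the true center, so a medoid-based note would fire on perfect data.)

Radial distances are pooled across compartments (per-compartment profiles
are available) and smoothed with a Gaussian KDE, bandwidth 8 Å over a 10 Å
histogram bin; peaks need 50 Å separation and 5% prominence. With layer gaps
near 100 Å these settings have roughly a ten-fold resolution margin; shells
closer than about twice the bandwidth may merge, which is visible (the peak
count is reported) rather than silent. Each particle is assigned to its
nearest peak when within half the smallest inter-peak gap. The radial angle
θ uses a 2.5° bin over [0°, 90°]; its mode is the midpoint of the bin with
the highest smoothed density, so a planted 15° tilt is reported as 16.25°
(the 15–17.5° bin) — within the discretization by construction. Whether the
experimental ~15° figure is a mode or a mean is not stated in the source
material; both are reported, and the mode is what the recovery checks use.
Particles within 20 Å of the center have an ill-conditioned radial vector
and are excluded from angular statistics.

## String analysis

Two particles are tandem iff (i) their fourfold axes are parallel or
antiparallel within 20°, (ii) each axis lies within 25° of the displacement
between them (the fourfold axis runs along the string), and (iii) their
separation is in [85, 130] Å — a window around one Rubisco diameter. The
tolerances are generous at the generator's jitter scale and all
config-exposed. Strings are maximal simple paths in the tandem graph after
branch resolution: edges are accepted in order of increasing collinearity
score (the sum of the two axis–displacement angles, ties broken on particle
order) while both endpoints have fewer than two string neighbors and no
cycle closes. This replaces the manual inspection used in the original
workflow with a deterministic, reproducible rule; an exhaustive maximal-path
enumerator confirms it on hundreds of random ≤ 12-particle instances.

Detection keeps strings of length ≥ 2 so that dimers are observable and the
"fewer than 3 in a row" classification boundary is decidable; length
statistics therefore include dimers, matching histograms whose string
lengths start at 2. Classification per compartment uses the maximum
detected length L: `random` (L < 3), `short` (3 ≤ L ≤ 6), else `moderate`
or `high`. The published class boundaries leave L = 7 unassigned ("3–6"
vs "> 7"); this artifact uses ≥ 7 for the upper classes, for contiguity.
The moderate/high distinction was originally made by visual inspection;
here it is an explicit surrogate — `high` iff at least 5 strings reach
length ≥ 7 — documented as this artifact's definition, not the original one.

String coordination declares two strings of a compartment adjacent when
their axes are parallel within 20° and their perpendicular
centerline–centerline distance is within ±30% of the bundle's lattice
spacing, estimated as the median nearest parallel-string distance. In a
hexagonal bundle this captures the 6 first-ring neighbors and excludes the
√3-ring; whether the original "surrounded by 6 strings" observation was
distance-based or visual is unstated, so the distance rule is again this
artifact's definition. The modal coordination is taken over strings with at
least one parallel neighbor; for bundles of at least one full ring it
reflects the interior coordination.

The population summary reports the ordered fraction (moderate + high) and
the fraction of particles lying in strings of length ≥ 3 within
ordered-class compartments — the same "in these carboxysomes" universe used
for the published ~8% figure.

## The synthetic generator

The generator is the package's acceptance surface: its presets *are* the
study conditions, and every analysis stage is validated by recovering what
was planted.

* **cyanobium preset** — three shells at 208/308/413 Å, counts
  Normal(224, 26) clipped to [100, 300], split across shells in proportion
  to shell area, placed by rejection sampling with a 90 Å minimum 3D
  separation; each fourfold axis is the radial direction tilted 15° toward
  a uniform random azimuth with a uniform spin.
* **halo preset** — counts Normal(274, 72) clipped to [50, 450] in a 500 Å
  compartment; string count Normal(12, 6) clipped to [2, 35]; lengths
  Normal(5, 2) rounded and clipped to [2, 9]; strings on a hexagonal
  lattice (spacing 110 Å) perpendicular to a random bundle axis, centered
  in the compartment, particles stacked at 105 Å per step with a 7.3°
  twist; the remaining budget is disordered background. 105/110 Å are
  approximate Rubisco height/width — the source states only "close to the
  diameter of Rubisco" — and both are config-exposed, never hard-coded in
  any analysis.
* **population preset** — a planted class per carboxysome drawn from the
  mix (0.62, 0, 0.19, 0.19): no strings for `random`, 1–4 strings of
  length 3–6 for `short`, one long string (length 7–9) for `moderate`,
  five for `high`. The published statistics are mutually inconsistent if
  taken together (12 ± 6 strings of length 5 ± 2 out of ~274 particles is
  ~22% in strings, not ~8%), so the two regimes are deliberately separate:
  the plain halo preset carries the string-count/length distributions, and
  the population preset's sparser ordered-class regimes are calibrated so
  that planted strings hold ≈ 8% of ordered-compartment particles
  ((7.5 + 5·7.5)/2 ≈ 22.5 of ~274). This calibration is the generator's
  definition of the published class mix, fixed before any recovery test
  was run.

Noise: positional jitter is iid Gaussian per coordinate (default 4 Å;
no experimental value exists, this is an artifact choice), angular jitter
is a random rotation with an iid Normal rotation vector (default 3° per
component), false positives are placed outside the compartment at a
configurable rate with scores Uniform(0, 0.12) against Uniform(0.1, 0.3)
for true particles, mirroring the displayed cross-correlation range.

Because the analysis *defines* the compartment center as the particle mean,
each synthetic compartment is built with its sample mean exactly at the
planted center: shell presets alternate a rigid re-centering with a radial
re-projection until convergence (keeping every particle exactly on its
shell), and bundle presets apply the rigid re-centering alone (preserving
string and lattice geometry exactly). Without this, zero-noise identity
tests would inherit an O(r/√n) center error that has nothing to do with the
analysis under test.

One pseudo-random stream per generation call, seeded explicitly and
restored afterwards; identical config + seed reproduces tables bit for bit.

What the generator does **not** emulate: shell geometry (no CsoS1/CsoS4
facets — compartments are spheres), linker-protein binding, missing-wedge
anisotropy, per-tilt alignment errors, score correlations with local
crowding, and duplicate picks. Passing recovery tests therefore demonstrate
correctness of the measurements under the stated geometric model, not
robustness to every pathology of real tomograms.

A genuine feature worth knowing: radially aligned particles on *adjacent
concentric shells* satisfy the tandem restraints (separation ≈ 100 Å, both
axes radial, hence parallel and along the displacement), so layered data
yields incidental dimers and occasional cross-layer triples, and disordered
halo background contributes roughly one incidental dimer per carboxysome.
Their folded twists are near-uniform on [0°, 45°]. This inflates the string
*count* mean slightly above the planted value while leaving the ordered
classification (which needs length ≥ 3) essentially untouched; the
recovery tests budget for it explicitly.

## Numerical choices and degenerate inputs

Rotation matrices are validated (orthonormality and determinant at 10⁻⁶) on
every read; Euler recovery handles the gimbal degeneracies (tilt 0°/180°)
by convention psi = 0. Quaternion extraction uses the largest-pivot rule.
Empty tables, empty compartments, singleton compartments (no neighbor
distances), compartments under 4 particles (excluded from distributions,
flagged), r < 20 Å (θ undefined), and zero detected strings (undefined
means flagged as NA) are all handled without error. Rejection sampling
proposes candidates in batches and fails with an instructive error when a
requested density is infeasible at the minimum separation; shell
occupancies above the random-sequential-adsorption saturation (~55% disc
coverage) cannot be generated, which caps per-shell counts well above the
preset regime.

Problem sizes in tests and the acceptance script — 25 layered carboxysomes
(~5,600 particles), 100–200 bundle-preset carboxysomes (~26,000–55,000
particles), 500 oracle instances, 1,000 orbit-enumeration pairs — were
chosen so each recovered statistic has sampling error comfortably inside
its tolerance while a full run stays in the tens of seconds on one core.

## Known limitations

* The center-as-mean definition is deliberately faithful rather than
  robust; heavily truncated or asymmetric compartments skew it (the
  mean/median note is the guard, 30 Å is its only threshold).
* KDE peak radii inherit a small positive bias O(σ²/r) from the radial
  Jacobian at strong jitter; at the preset noise (≤ 6 Å on 200–400 Å
  shells) it is well under the reporting tolerance.
* The string detector's greedy branch resolution is order-deterministic but
  not globally optimal; the exhaustive oracle bounds its behavior only on
  small instances.
* The moderate/high surrogate and the lattice-distance adjacency rule are
  explicit re-definitions of originally visual judgments; numbers that
  depend on them are comparable across runs of this package, not
  necessarily across publications.
* Sign of the twist (handedness of the spiral) is intentionally not
  reported: the canonical fold discards it, and a right-handed frame flip
  would be needed to make it meaningful across heterogeneous tool chains.
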