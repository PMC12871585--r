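---
title: "Microwell-array time-lapse analysis with conewell"
author: "conewell authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microwell-array time-lapse analysis with conewell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conewell)
```

# Scope and model of the data

`conewell` analyzes time-lapse images of conical microwell arrays used for
single-cell clone discovery: arrays of cavities (65 µm bottom diameter on a
130 µm pitch) molded at the bottom of a 96-well plate, each well holding
thousands of microwells. Cells are seeded stochastically, imaged at regular
intervals (typically every 4 h) in brightfield plus fluorescence channels,
and microwells are selected for robotic retrieval by hierarchical gating on
per-microwell features: cell count, growth, surface markers, and cytokine
secretion captured on the microwell walls.

The package covers the computational chain only — lattice detection,
registration, per-microwell quantification, growth and secretion
statistics, gating, pick-list generation, and loading/enrichment models.
Instrument control, learned detectors, and wet-lab protocol steps are out
of scope; where the production instrument uses trained neural detectors,
`conewell` substitutes classical detectors behind the same interfaces (see
below).

Image stacks follow the OME-NGFF layout with the axis order fixed to
TCZYX; `openStack()` refuses any other axis order rather than silently
transposing. Because no R implementation of zarr exists, the package
carries its own minimal zarr v2 directory-store layer (uncompressed
float64 chunks, one plane per chunk, standard `.zarray`/`.zattrs`
metadata), which any compliant zarr reader can open. Coordinates are
0-based `(y, x)` pixels with the origin at top-left; micrometer quantities
are converted only at the boundary via the pixel size.

# The synthetic scene generator

Every stage of the pipeline is testable offline because `renderScene()`
emulates the instrument output with complete ground truth. What it
emulates, and how:

* **Loading.** Each cell lands in a uniformly random microwell
  (`simulateLoading()`), i.e. occupancy is multinomial and converges to
  Poisson(λ) — the model under which single-cell occupancy is maximized at
  one cell per microwell.
* **Growth.** Each occupied microwell draws a division rate once from a
  lognormal distribution and grows deterministically:
  `n(t) = round(n0 · 2^(r · t_days))`, rounding half-up, with zero an
  absorbing state. Deterministic-exponential growth with a random
  per-microwell rate matches the model class the growth estimators fit,
  which keeps recovery tests interpretable; per-division stochasticity is
  deliberately not modeled.
* **Appearance.** Microwells render as radially symmetric dark cones with
  a darker bottom disk in brightfield (the darkest pixel is the center,
  which anchors detection tests); cells are dark 10 µm blobs placed
  without overlap at the microwell bottom, with matching additive
  fluorescence in their marker channel.
* **Secretion.** Positive microwells accumulate a rotationally uniform
  annular signal at a constant rate (default 10 AU/h on a 100 AU
  background); cross-talk victims receive a one-sided 90° arc at 60% of
  that rate with random orientation, emulating cytokine captured from a
  neighbor.
* **Drift and noise.** A global integer stage drift per timepoint
  translates the whole frame before i.i.d. Gaussian noise is added.

Defaults that the underlying study does not pin down were chosen once as
field-realistic values and not revisited: lognormal shape σ = 0.35 (the
observed rate distributions are wide), death fraction 5%, secretion rate
10 AU/h, arc width 90°, cross-talk amplitude 60%, brightfield background
1000 with cone depth 300, fluorescence background 100 with noise σ = 5.
Secretion/cross-talk labels are planted with exact counts
(`round(fraction · n)`), so tests can assert set equality rather than
sampling bounds.

Two presets encode the study conditions: `"nalm6_default"` (Poisson
loading at λ = 1, 4-day movies at 4-h cadence, lognormal rates with median
0.8 divisions/day) and `"peptide_pulsed"` (co-cultures of exactly two
cells per microwell, 24-h movies, 40% secretion-positive, 5% cross-talk
victims).

What the generator does **not** emulate — and hence what passing tests do
not show about real data: optical blur and conical-wall optics, uneven
illumination, focus drift, cell migration between microwells, debris and
apoptotic morphologies, per-division stochasticity, and photobleaching.
The classical detectors below are tuned to be exact on this clean imagery;
on real images they would need the pluggable learned detectors the
interfaces anticipate.

# Lattice detection and registration

`detectGrid()` replaces the instrument's learned microwell detector with a
classical pipeline: a zero-mean radial matched filter (radius 0.4 pitch),
local-maxima peak picking over a 0.7-pitch neighborhood with a half-max
floor, robust pitch estimation from median nearest-neighbor spacing
(rejected if >20% from the configured pitch), rotation from
nearest-neighbor angles folded into (−45°, 45°] (ties broken toward the
smaller angle; rotations beyond ±5° are out of scope), and sub-pixel
refinement by three iterations of median-subtracted intensity centroids.
IDs are assigned row-major after rotation correction and are stable by
construction: `registerTimepoint()` only estimates a whole-frame integer
translation (FFT cross-correlation, with a peak z-score floor of 5 below
which a warning is issued and zero shift assumed), it never re-identifies
microwells. On noiseless scenes detection is pixel-exact; the tests hold
it to ≤0.5 px mean error.

Accessibility: the picker cannot reach microwells near the well perimeter.
The well footprint is the bounding circle of detected centers and the
accessible region is the concentric circle holding 75% of the footprint
*area* (radius fraction √0.75 ≈ 0.866). The area interpretation was chosen
because 75% of ~3,958 microwells per well ≈ 2,970, closest to the ~2,800
reachable microwells quoted for the instrument; whether that number
reflects an area fraction, a radius fraction, or a tip-clearance margin is
not derivable from the available description, so the fraction is a
configuration parameter.

# Cell counting and marker quantification

`countCells()` substitutes for the instrument's learned instance
segmentation: the smooth conical background is removed by subtracting a
running median (window set by the largest admissible object, so blobs
vanish from the estimate while the cone gradient is tracked), residual
dark blobs are thresholded at half the residual maximum, split by
watershed on the distance transform, and passed through the size gate —
equivalent diameter between 5 and 20 µm by default. The upper bound
removes oversized artifacts; the lower bound removes debris. Touching
cells that the watershed cannot separate are merged — a documented
limitation; the tests require ≥95% per-microwell count accuracy for
non-touching cells at λ ∈ {0.5, 1, 2}. Above a foreground density limit
the count saturates and the crop is flagged `crowded`; dense colonies
beyond ~50 cells are reported as saturating counts, not resolved.

Fluorescence is quantified through the brightfield mask template: each
cell's mean intensity per channel minus the out-of-mask median of the same
crop (robust to secretion-ring light at the crop edge). Marker thresholds
are experiment-specific; when none is given, `markerThreshold()` proposes
background median + 5·MAD.

# Growth statistics

Two estimators are computed per microwell, then gated jointly:

* `fitDivisionRate()` — ordinary least squares of log2(count) on time in
  days, so the slope is directly in divisions/day. The fitting method is a
  package choice (the study does not state one); zero-count timepoints are
  excluded rather than imputed since the logarithm is undefined there, and
  trajectories with fewer than two usable points are flagged instead of
  fitted.
* `normalizedMeanCount()` — mean count over all timepoints divided by the
  t0 count. The averaging weights are taken as uniform and the t0 term is
  included; both are documented choices (switchable for the t0 term) where
  the source description is ambiguous.

`classifyProliferative()` requires both `r ≥ 0.25` divisions/day and
`g ≥ 1.2` by default. The two estimators fail differently (the fit is
sensitive to single-timepoint miscounts; g is damped by early timepoints),
so the conjunction suppresses artifacts either alone would admit. Both
thresholds are interactive analysis choices in practice; they are exposed
in configuration and recorded in the pipeline provenance.

# Secretion rings and the symmetry gate

Cytokine captured on the microwell walls is quantified in an annulus
between radius fractions 0.25 and 0.475 of the pitch — i.e. from half the
bottom diameter to just inside the rim; the exact radii used on the
instrument are not published, so the defaults tie to the cone geometry and
are configurable. The relative signal `S(t) = I(t) − I(t0)` cancels any
additive background. Positives are called when S exceeds a threshold
*and* the ring is rotationally uniform.

The symmetry statistic is the coefficient of variation of the means of 8
equal angular sectors (the concept comes from the instrument workflow; the
formula is this package's). One numerical subtlety drives the
implementation: computed on the raw crop, a dim one-sided arc of amplitude
A over background B has sector-CV ≈ 0.43A/(B + A/4), which stays below
any practical gate while A < ~1.6B — dim cross-talk would leak through.
`quantifySecretion()` therefore evaluates the score on the temporal
difference crop (t minus the registered t0 crop), for which the arc's CV
is ≈ √3 regardless of amplitude and a uniform ring's CV is noise/A. With
the default gate at 0.5 the separation is orders of magnitude. At t0 the
difference is identically zero and the score is the `Inf` sentinel
(harmless: S(t0) = 0 can never cross the intensity threshold).

The intensity threshold defaults to control-derived: mean + 5·SD of S over
occupied-but-unstimulated microwells at the matched timepoint
(`deriveSecretionThreshold()`); an absolute override exists, and having
neither is a configuration error. Positivity is called at a single
timepoint by default (persistence across consecutive timepoints is
available as a window option); the first positive timepoint is recorded.
Eight sectors balance angular resolution against pixels per sector
(~270 at 2 µm/px).

# Gating, pick lists, and loading statistics

Gate trees are conjunctions of threshold comparisons over
(feature, timepoint) pairs — selectors `@t0`, `@first`, `@last`,
`@any(t>=H)` — with disjunction via sibling nodes; this covers the
published cascades without a general expression language, and evaluation
is required (by test) to equal brute-force row filtering. Printed gate
percentages use half-up rounding (`gateFraction()`), the convention under
which 47,597/137,758 prints as 35%.

Pick lists interleave labels in alternating order, insert blank controls —
empty accessible microwells at seeded-random positions, used to detect
carry-over contamination — and convert coordinates to micrometers using
the last registered shift. The CSV schema is this package's (the
instrument's native format is unpublished). Accessibility is a hard
invariant: an inaccessible selection is an error, never a silent drop.

Loading statistics use the closed-form Poisson model (`occupancyPmf()`,
`expectedSingles()`; PMF tables truncate at
`max(20, ⌈λ + 10√λ⌉)` with the tail folded into the last bin).
The figure of ~1,300 expected singles sometimes quoted for 4,000 loaded
cells is not used as a numeric oracle because the microwell denominator
behind it is unstated; the closed form itself is the contract, and its
optimum at `nCells = nMicrowells` is verified numerically. Enrichment
analysis (`enrichmentTable()`, `dominantAntigen()`) consumes precomputed
count tables; read alignment is out of scope. Fold enrichment for
zero-bulk members is an `Inf` sentinel, not an exception.

# Pipeline, determinism, and problem sizes

`runPipeline()` chains detect → register → quantify → growth → secretion →
gate → picklist, writes every artifact as CSV/JSON into an append-only
output directory, and emits a provenance record containing the package
version, seed, and every threshold used. All randomness flows from
explicit seeds, so a re-run with identical configuration is
byte-identical — the tests assert this on the feature table.

The test and acceptance workloads use desk-scale problem sizes chosen to
exercise every code path at full fidelity: 2 µm/px rendering (65 px
pitch), scenes between 3×3 and 25×20 microwells, 2,000 trajectories for
growth recovery, and 500 co-culture microwells for secretion recovery.
The growth-recovery check perturbs counts with ±1 miscounts at 10% of
timepoints to emulate segmentation noise before fitting.

# Known limitations

* Classical detectors are tuned for the clean synthetic imagery; real
  images need learned models plugged into the same interfaces.
* Touching cells merge; dense colonies saturate with a `crowded` flag.
* Registration is global translation only: no rotation beyond ±5°, no
  non-planar distortion, no per-field flat-field correction.
* Secretion quantification is wall-capture only (no bead-based assay) and
  reports arbitrary units, not concentrations.
* Z stacks are read and max-projected; downstream analysis is 2-D.
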