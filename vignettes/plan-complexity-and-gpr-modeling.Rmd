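---
title: "Plan complexity analytics and GPR modeling for VMAT QA"
author: "planqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plan complexity analytics and GPR modeling for VMAT QA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planqa)
```

## The problem

Patient-specific quality assurance for volumetric modulated arc therapy
(VMAT) compares a measured dose distribution against the planned one
with the gamma index; the gamma passing rate (GPR) against an action
limit classifies the plan as pass or fail. Because the measurement is
costly, the GPR is commonly modeled from the plan itself: every
property of the delivery — aperture shapes, leaf kinematics, monitor
unit (MU) distribution — is encoded in the DICOM-RT control-point
sequence, and complexity metrics summarizing that sequence correlate
with deliverability. `planqa` implements the plan model, two families
of features (48 conventional whole-plan metrics and a large
control-point-resolved histogram set we call planomics), a 2-D gamma
engine, a stability feature-selection pipeline, the repeated
train/test evaluation protocol for GPR regression and pass/fail
classification, and a synthetic cohort generator that makes the whole
stack testable without clinical data.

## The plan model

A plan is a `MachineSpec` plus a list of arcs; each `Arc` stores
per-control-point gantry angles, cumulative meterset weights in [0, 1],
two leaf-bank position matrices (mm, IEC 61217; bank A on the negative
side) and a jaw matrix. Everything downstream is computed from this
model, so its invariants are enforced at construction: weights
non-decreasing from 0 to 1, opposed banks never crossing beyond a small
tolerance, bank dimensions matching the machine's leaf count.

Two derived quantities matter everywhere:

* **Segment timing.** A VMAT segment is delivered at whichever limit
  binds: $\Delta t_i = \max(\Delta MU_i / \dot{MU}_{max},
  \Delta\theta_i / \dot\theta_{max})$. Machine maxima are configuration,
  not constants (600 MU/min and 6 deg/s for the default C-arm machine,
  800 MU/min for the ring-gantry entry); they only set the timing
  denominator for speeds and accelerations.
* **Aperture geometry.** A leaf pair is dosimetrically open iff its gap
  exceeds the machine's minimum leaf gap (2 mm by default) *and* the
  pair's row intersects the y-jaw span; open gaps are clipped to the
  x jaws (`clipToJaws = TRUE` by default — whether a clinical in-house
  script clips is usually unknowable, so the flag is exposed). Area is
  the summed clipped rectangle area. The perimeter follows the jagged
  outline of the union of leaf-row rectangles, computed exactly from
  row-interface overlaps rather than a raster. The union aperture area
  (UAA) and the edge-zone area used by EAM are likewise computed
  exactly — UAA by a sweep over y-bands of the rectangle union, EAM by
  erosion with a square structuring element via interval arithmetic —
  and the tests compare both against 0.1 mm pixel-counting oracles.

### DICOM-RT

Plans are read from and written to explicit-VR little-endian DICOM-RT
Plan files covering the subset the model represents (beam sequence,
per-control-point MLC/jaw positions, meterset weights, fraction group
and dose reference). The writer's output is verified in the tests both
by round-trip identity and by parsing with an independent DICOM toolkit.
Cumulative weights are normalized by the final cumulative meterset
weight on read; the treatment machine is resolved by name against a
configurable machine table (a YAML example ships in `inst/extdata`).
The clinical description of a 120-leaf MLC with 5 mm central and 10 mm
outer leaves over a 40 cm field implies 60 opposed pairs; the default
`TrueBeam`/`VitalBeam` geometry is built accordingly, and the
dual-layer ring-gantry MLC is deliberately mapped onto a single-layer
57-pair spec because no defensible combination rule exists for a
single-layer model.

## Conventional features (48)

The vector follows the established metric families: modulation indices
$MI(f) = \int_0^f z(x)\,dx$ where $z(x)$ is the fraction of speed
(acceleration, weighted-speed) samples exceeding $x\sigma$, integrated
by trapezoid at step 0.01 for $f \in \{0.2, 0.5, 1, 2\}$; binned
speed/acceleration proportions on the grids $a = 0, 0.4, \ldots,
2.0$ cm/s and $b = 0, 1, 2, 4, 6$ cm/s$^2$ with the last bin
right-closed and absorbing overflow (real plans exceed the grid);
small-aperture scores at 5/10/20 mm; MCS from per-control-point
leaf-sequence variability (LSV) and aperture-area variability (AAV);
plan area/irregularity/modulation; edge metrics; leaf travel; leaf
gaps; dose rate statistics; and the prescribed fraction dose.

Decisions the definitions leave open, and how this package fixes them:

* **Moving-leaf mask.** Speeds are sampled per (leaf, segment) only for
  pairs open at at least one flanking control point; the mask is a
  flag (`movingMask`) because sampling all 120 leaves is equally
  defensible. Zero-duration segments are excluded and counted.
* **Acceleration denominators** use the centered segment-mean
  $\bar{\Delta t}$ because segment durations are unequal.
* **LSV flat-bank convention.** A bank whose open-leaf positions span
  zero range (or a single open leaf) scores 1: zero positional
  variability is the smoothest possible sequence, and the convention
  avoids 0/0. This is what makes a static rectangular arc score
  MCS = 1 exactly.
* **MU weighting.** Per-control-point MU comes from meterset-weight
  differences, with the first control point of an arc taking the first
  segment's MU; plan-level metrics weight control points by MU and arcs
  by arc MU. Splitting a control point's MU across two identical copies
  leaves every MU-weighted metric unchanged (tested to 1e-9).
* **Total-modulation weighting.** The per-segment weight is
  $(1 + |\Delta \dot{MU}| / \dot{MU}_{max})(1 + |\Delta\dot\theta| /
  \dot\theta_{max})$, a normalized delivery-variation factor; the exact
  historical weighting is not recoverable from published summaries, so
  the choice is documented here and isolated in one function.
* **Edge metrics.** EM uses unit coefficients (perimeter/area); CAM and
  EAM use an edge-zone width $d_{edge} = 5$ mm, exposed as an argument.
  C/A computes perimeter/area per connected aperture component
  (consecutive open pairs with overlapping intervals) and averages.
* **MAD** measures pair-midpoint asymmetry about the area-weighted
  aperture centroid of its control point.
* **ADR/SDR** derive from $\Delta MU / \Delta t$ rather than planned
  dose-rate tags, so they are defined for any file.

## Planomics features (2,476)

Per control point the package computes MU, aperture area (AA),
MUAP = MU $\times$ AA, the circle-normalized irregularity PSR
($P^2 / 4\pi A$, 0 at closed apertures), the mean open-leaf speed of
the flanking segments (SF), the segment dose rate (RF) and the mean
open gap (GAP). Each metric series is then histogrammed on a fixed
grid, in up to two variants: **T**, the proportion of control points in
each bin, and **TR**, the MU-weighted proportion. Out-of-grid values
are absorbed into the edge bins, so each (metric, variant) block sums
to exactly 1 for a nonempty plan. Feature names follow
`<METRIC>_<VARIANT>_<lo>-<hi>`.

The shipped default grid is:

| metric | range | width | bins | variants |
|---|---|---|---|---|
| MUAP | 0–60000 MU mm² | 200 | 300 | T, TR |
| MU | 0–20 MU | 0.1 | 200 | T, TR |
| AA | 0–30000 mm² | 200 | 150 | T, TR |
| GAP | 0–150 mm | 1 | 150 | T, TR |
| PSR | 0–47 | 0.25 | 188 | T, TR |
| SF | 0–2.5 cm/s | 0.01 | 250 | T |
| RF | 0–800 MU/min | 3.2 | 250 | T |

for a total of $2 \times (300 + 200 + 150 + 150 + 188) + 250 + 250 =
2{,}476$ features. The grid is a reconstruction pinned in a versioned
configuration: the metric families, the MUAP dominance, the 200-unit
MUAP bin width implied by names like `MUAP_TR_24200-24400`, and the
T/TR pairing are all honored, but bin-level equivalence with any
specific clinical implementation is explicitly *not* claimed, and the
T = count-weighted / TR = MU-weighted assignment is a documented
interpretation isolated in `defaultPlanomicsConfig()`. Custom grids are
first-class (`planomicsConfig()`).

## The gamma engine

`gammaMap()` computes a reference-anchored 2-D gamma with global
normalization (normalization dose = maximum of the reference plane;
where the normalization point of a vendor system is unstated, the
maximum is the standard choice). Reference points below the low-dose
threshold (10% by default) are not evaluated. For each evaluated point
the minimization runs over a candidate stencil of step
$d_{DTA}/10$ anchored at the reference point within a radius
$3\,d_{DTA}$, with the evaluated dose bilinearly interpolated at each
candidate. Anchoring the stencil at the reference point guarantees that
identical planes give $\gamma = 0$ exactly; both the step and radius
factors are arguments, and an exhaustive nested-loop oracle in the test
suite confirms equivalence to 1e-6 on random plane pairs. Pass/fail is
boundary-inclusive ($GPR \ge$ action limit passes), following standard
QA convention; the default criteria are 3%/3 mm, 3%/2 mm and 2%/2 mm
with a 10% threshold and strict action limits 99/98/95%.

The analysis is deliberately asymmetric in its arguments (the reference
defines both grid and normalization); the tests include a constructed
pair whose GPR changes when the planes are swapped.

## Feature selection

`selectFeatures()` implements a stability protocol: remove constant
columns; 100 times, draw 80% of the training rows without replacement,
drop features constant on the subsample, score the rest with the
univariate F statistic (simple-regression F for continuous GPR, one-way
ANOVA F for pass/fail) and keep the top 100; shortlist the 30 features
most frequently kept (ties broken by mean F, then name); and reduce to
k = 10 by greedy minimum-redundancy-maximum-relevance. k = 10 reflects
the usual rule of keeping the model dimension below ~10% of the sample
size. The resampling fraction and per-iteration keep count are not
canonical and are exposed as arguments. The "zero-threshold variance
filter" step is interpreted as unsupervised constant-feature removal —
the only reading under which the step is unsupervised.

The MRMR score is the difference form: relevance (F normalized by its
maximum over the shortlist) minus the mean absolute Pearson correlation
with the already-selected set. Normalizing relevance to [0, 1] puts it
on the same scale as the redundancy penalty, so an exact duplicate of
an already-selected feature (redundancy 1) can never be picked while
any non-redundant candidate with positive relevance remains.

Selection only ever sees the training partition; the test suite
verifies that scrambling test-cohort labels changes nothing about the
selected set.

## Models and evaluation

* **Regression** (predicting the continuous GPR): gradient-boosted
  trees, tuned by randomized search (60 draws by default) over learning
  rate, tree count, depth, row subsampling and L1 regularization,
  scored by 5-fold cross-validated mean absolute error. The no-search
  default configuration (learning rate 0.12, 58 trees, depth 3,
  alpha 0.12) is always among the candidates. Accuracy is reported as
  the absolute prediction error $APE = |GPR_{pred} - GPR_{meas}| /
  GPR_{meas} \times 100\%$ — and, because published APE values can be
  read either as that ratio or as percentage-point differences, the
  report carries both forms (`apeTestMean` and `maeTestPts`).
* **Classification** (pass/fail at the action limit): linear least
  squares on $\pm 1$ targets with L2 regularization via glmnet
  (alpha = 0, standardized features), the penalty chosen by 5-fold
  cross-validated AUC over a log grid of sklearn-style alpha values
  from $10^{-2}$ to $10^3$ (the grid contains 1.0 and 31.6; glmnet's
  lambda is alpha/n). AUC always comes from continuous decision scores,
  never hard labels.
* **Protocol**: repeated 70/30 splits (20 repeats for classification by
  default — the procedural statement; a single split is the regression
  default), optional downsampling of the training majority class
  (default on, mirroring clinical practice with imbalanced QA data),
  selection refit inside every repeat on training data only, and
  single-class test draws redrawn with a logged count.

## The synthetic cohort generator

The generator emulates the study conditions everything above is tested
under: 200-plan cohorts; 2–7 full arcs per plan at 2.0341 deg
control-point spacing (178 control points per arc); the 120-leaf MLC
geometry; 6 MV-scale fraction doses of 1.8–2.2 Gy. A per-plan
modulation level $m \in [0.1, 0.9]$ drives band-limited leaf-trajectory
noise around a rectangular base aperture (clamped to the 2.5 cm/s leaf
speed limit and the minimum gap), static per-pair shape irregularity,
MU dispersion (a Dirichlet draw whose concentration falls with $m$) and
total MU. Modulation 0 degenerates to a static rectangular arc (MCS = 1,
ALT = 0), which the tests use as an anchor. Dose-plane pairs are built
by accumulating MU-weighted binary aperture fluence at 1 mm — no
transmission, penumbra or scatter, because the gamma engine needs
spatial structure, not dosimetric realism.

GPR labels follow
$GPR_c = \mathrm{clip}(base_c - scale_c \cdot s + \epsilon_c, 0, 100)$
with the complexity score
$s = 2(1 - MCS) + 3\,SAS5 + 12\,MUAP_{mid} + 0.4\,SDR/100 +
50\,(1 - LSV)$,
where $MUAP_{mid}$ is the MU-weighted mass of control-point MUAP in
the 8,000–16,000 MU mm² band. Two deliberate design choices shape this
score. First, the dominant term is the MUAP band mass — a quantity the
planomics histograms resolve directly but the conventional set captures
only weakly (its multivariate $R^2$ from the 48 conventional features
is about 0.2 on default cohorts) — so planomics features genuinely
carry label signal beyond the conventional set. Second, the
conventional-unique term uses LSV, empirically the conventional metric
*least* reconstructible from the planomics histograms ($R^2 \approx
0.54$, against 0.85–1.0 for MCS, SDR or leaf travel); with both terms
present, hybrid feature sets are informative beyond either single set,
which is exactly the qualitative structure the classification protocol
is expected to recover (mean test AUC: hybrid $\ge$ planomics $\ge$
conventional at all three criteria). The per-criterion intercepts,
scales and noise SDs (base 125.1/141.36/175.97, scale 0.86/1.433/2.722,
noise 0.9/1.6/3.0) were calibrated once so that default cohorts
resemble clinically reported GPR distributions — means near
98.7/97.3/93.8% with growing spread at tighter criteria, and both QA
classes present at the 99/98/95% action limits with prevalences near
54/48/40% passing — and then frozen. All parameters live in
`defaultLabelModel()` and are recorded in cohort metadata.

What passing tests on this cohort do and do not show: they demonstrate
that the pipeline recovers constructed complexity-to-GPR couplings of
realistic magnitude under realistic plan geometry; they cannot certify
performance on clinical EPID measurements, where the physics linking
complexity to deliverability is richer than any linear label model.

## Numerical choices and problem sizes

Tolerances: histogram block sums and MU-split invariance at 1e-9;
gamma-oracle equivalence at 1e-6; exact-geometry oracles (perimeter,
UAA) at 1e-9 on grid-aligned fixtures. Degenerate inputs follow fixed
conventions: closed apertures have area and perimeter 0 and are
excluded from ratio metrics with a logged count; zero sample SD makes a
modulation index 0; an empty kinematics record yields zero histograms
with a warning; an all-closed plan is an error ("no deliverable
aperture"). Ties in selection break by mean F then name order so
reports are deterministic; all randomness is derived from user seeds
through a single sub-seed function, and every pipeline stage is
byte-identical under identical seeds.

The shipped test and acceptance runs use a 200-plan default cohort, 50
random 21$\times$21 plane pairs for the gamma oracle, and 20-repeat
classification; feature extraction runs in well under a second per
arc on one CPU.

## Known limitations

* The planomics grid is a documented reconstruction; individual bins
  are comparable across plans analyzed by this package, not across
  implementations.
* The DICOM codec reads explicit-VR little-endian RT Plans only — the
  transfer syntax it writes; clinical exports in implicit VR would need
  transcoding upstream.
* Dual-layer MLC geometry is not modeled; ring-gantry plans map onto a
  single-layer spec.
* The gamma engine is 2-D, reference-anchored and globally normalized;
  3-D gamma, local normalization and measurement-uncertainty handling
  are out of scope.
* The fluence rasterizer ignores transmission and penumbra by design.
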