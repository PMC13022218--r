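---
title: "Two-stage random-forest mapping of wetland nutrients: model, assumptions, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage random-forest mapping of wetland nutrients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wetstage)
```

## The problem and the model

Monthly grab samples at a handful of stations cannot describe how nitrogen
and phosphorus concentrations vary across a wetland complex and through the
seasons. `wetstage` implements a hybrid strategy that splits the prediction
problem into two regressions operating at different spatial scales:

* **Stage 1 (baseline).** A random forest regresses observed concentration
  on *discrete, per-wetland* attributes: area (km²), perimeter (km), the
  Shape Complexity Index SCI = P/A, the Polsby–Popper compactness
  PPS = 4πA/P², 7-day trailing mean rainfall (mm) and temperature (°F),
  and NLCD-style land-use percentages (open water OP, developed DA, barren
  BL, forest FO, shrub/scrub SS, herbaceous HB, hay/pasture HP, cultivated
  crops CC, woody wetlands WW, emergent herbaceous wetlands EHW). Its
  prediction is constant within a wetland for a given quarter: the
  landscape-scale level.
* **Stage 2 (residual correction).** A second, independent random forest
  regresses the stage-1 residuals r = y − ŷ₁ on *continuous, per-pixel*
  predictors sampled from quarterly mean composites: Sentinel-2-style
  surface-reflectance bands B2–B8A, B11, B12; NDVI = (NIR−Red)/(NIR+Red);
  NDWI = (Green−NIR)/(Green+NIR); EVI = 2.5(NIR−Red)/(NIR+6Red−7.5Blue+1);
  and SAR predictors in linear power: VV, VH, VV/VH, VH/VV, and
  SRVI = 4·aVV/(aVV+aVH).
* **Combination.** The final prediction is the per-pixel sum
  ŷ = ŷ₁ + r̂ (map algebra), exact to machine precision before the optional
  clip of negative concentrations to zero.

The additive split keeps each model interpretable: stage-1 importances rank
landscape drivers, stage-2 importances rank in-stream biophysical signals,
and the final map inherits both. The residual formulation assumes the two
scales combine approximately additively; multiplicative interactions
between landscape and pixel scales are not representable.

### Residuals for stage-2 training

In-sample random-forest predictions are nearly interpolating, so in-sample
residuals are close to zero and carry almost no signal. By default the
stage-1 residuals handed to stage 2 are therefore **out-of-bag** residuals
(`residual_source = "oob"`): each training row is predicted only by trees
that did not see it, which puts the residuals on the scale at which the
baseline actually errs. `residual_source = "insample"` is available for
comparison. Rows that were never out of bag (possible only at very small
n) fall back to the in-sample prediction.

### SRVI numerator

The radar vegetation index is defined here with the co-polarised channel
in the numerator, SRVI = 4·aVV/(aVV+aVH), and is bounded in (0, 4). The
conventional cross-polarised form 4·aVH/(aVV+aVH) is available via
`srvi_numerator = "vh"` (the two complement each other to exactly 4); the
co-polarised form is the default.

## Temporal and spatial alignment

Scenes are composited per **calendar quarter** (Q1 = January 1 – March 31,
half-open date ranges, no overlap windows): every pixel of a quarter
composite is the arithmetic mean of the valid observations of that band in
the quarter, and a pixel with no valid observation is nodata. Derived
indices are computed **from the composited bands** (mean-then-index), not
averaged per scene — the two differ for nonlinear indices, and
mean-then-index matches treating the composite as the "mean environmental
state" the samples are matched to. SAR bands must be converted to linear
power *before* compositing (`db_to_linear()`); averaging dB values would
average logarithms.

Spatially, all bands live on one shared grid (default 10 m) with
pixel-center registration and half-open cells: a map point belongs to
column `1 + floor((x − origin_x)/pixel)` and row
`1 + floor((origin_y − y)/pixel)`. `resample_to_grid()` aligns coarser
bands by nearest-neighbour (default, categorical-safe) or bilinear
interpolation. No reprojection is implemented: all inputs must share one
CRS label.

Each water sample is matched to its quarter's composite at its coordinates
(`build_feature_table()`). Rows whose continuous block touches a nodata
pixel are **flagged, never dropped**: stage 1 can still use them (it needs
only discrete features), stage 2 excludes them, and prediction falls back
to the baseline with `provenance = "baseline_only"`.

## Validation

`split_train_test()` draws a seeded 70/30 split
(`|train| = round(0.7 n)`, exact, disjoint, exhaustive; optional
stratification). `metrics_report()` evaluates held-out rows on three
scales — the stage-1 baseline against observations, the stage-2 prediction
against the *realised* residuals y − ŷ₁, and the final sum against
observations — with r² = 1 − SS_res/SS_tot, RMSE, MAE, and the mean bias
error MBE = mean(ŷ − y) (positive = over-prediction). r² is reported as
`NA` when the observations have zero variance. The stage-2 column's scale
is an interpretation choice (the residual scale) and is recorded in the
metrics JSON metadata.

Model scope: with enough data the pipeline fits one model per
(year, quarter) (`scope = "per_quarter"`), mirroring the per-quarter
importance analysis; when any year-quarter has fewer than
`min_quarter_train = 20` training rows it falls back to a pooled model
whose stage-1 block gains quarter one-hot features so the baseline can
carry seasonal level shifts. The default 324-sample layout (27 rows per
year-quarter, 19 of them training) falls below that threshold, so the
pooled path is the usual one at this scale. Importance heatmaps
(`importance_heatmap()`) are always computed from per-(year, quarter)
stage fits and averaged over years within each quarter; ranks break ties
by descending score then feature name.

## The synthetic study generator

No field data ship with the package; `synth_study()` generates complete
study inputs from a known additive model so every stage is testable:

concentration = intercept + β·discrete + γ·continuous(pixel, month)
             + seasonal(quarter) + trend(year) + noise, truncated at 0.

* **Layout.** 3 wetlands × 3 stations (inlet/middle/outlet) × 36 monthly
  dates (2021–2023) = 324 records, on a 200 × 200-cell 10 m grid — the
  scale of a small monitored wetland complex. Wetlands are star-shaped
  radially perturbed circles placed along the grid diagonal with radii
  derived from the center spacing, so they are simple polygons and
  mutually disjoint by construction (~0.2–0.25 km² each, well under
  1 km²).
* **Land use.** The default `"bwg-like"` preset represents a mixed-use
  landscape: developed ≈ 26.2 %, cultivated crops ≈ 38.2 %, forest
  ≈ 14.7 % (±2 points of jitter), with the hay/pasture share spreading
  across wetlands and the remainder distributed over the other classes;
  percentages always sum to exactly 100. An `"independent"` preset draws
  every class independently per wetland (see *Validation design* below).
* **Imagery.** Each band is mean level + smooth static Gaussian random
  field + per-quarter anomaly field (correlation length 5 pixels ≈ 50 m,
  so stations ~100 m apart sample decorrelated values and point sampling
  is stable under small coordinate jitter) + a scene-wide monthly scalar
  shift + fine per-pixel noise. Modelling within-quarter variation as a
  scene-wide shift reflects that day-to-day differences between
  acquisitions are dominated by illumination and surface-moisture state,
  and it keeps many-replicate validation loops cheap. A shared
  "vegetation" latent with a Q2/Q3-peaking seasonal cycle couples into
  B8/B4 (hence NDVI), the red-edge bands, and the VV/VH ratio, so optical
  and SAR predictors co-vary coherently. Reflectances are clipped to
  [0, 1]; SAR is generated in dB with VV ≈ −11 dB above VH ≈ −18 dB, so
  the linear-power VV/VH ratio exceeds 1.
* **Concentration presets.** Nitrogen: intercept 0.3 mg/L, β on HP
  (0.03 mg/L per %), rainfall and temperature, γ on NDVI (1.2) and VV/VH
  (0.04), quarter sinusoid of amplitude 0.4 mg/L peaking Q2/Q3
  (summer nitrogen stress), noise σ = 0.05 mg/L; concentrations fall in
  ~0.5–3 mg/L. Phosphorus: smaller coefficients on HP and DA
  (source-loading from developed land), weak γ, a linear annual decline
  of 0.05 mg/L/yr emulating multi-year recovery, noise σ = 0.005 mg/L.
  Both are presets, not claims about any particular site. Truncation at 0
  is used instead of resampling; the truncation rate is recorded and is
  < 1 % under the default specs.
* **Truth.** Every component of every sample is stored losslessly
  (`truth`), and `synthetic_residual_field()` reconstructs the latent
  per-pixel residual field γ·continuous for any quarter composite, so
  recovery can be scored exactly.

What the generator does **not** emulate: SAR speckle statistics, clouds
and cloud shadows, atmospheric residuals, georeferencing error, real
hydrology. Passing the recovery tests therefore shows the estimator
recovers a known additive signal under realistic dimensions and noise —
not that any particular accuracy will be achieved on real imagery.

## Validation design choices

* **Parameter recovery.** Twenty replicate studies at the default
  conditions (σ = 0.05 mg/L) are each fit end-to-end; the final model's
  held-out r² exceeds 0.85 and exceeds the stage-1 r² in essentially all
  replicates — the stage-wise improvement the two-stage design exists to
  deliver.
* **Stage attribution** uses a deliberately stripped scenario: γ ≡ 0 and
  zero seasonal amplitude, so the target is purely discrete signal plus
  noise. Under it, stage 2's held-out r² stays at or below zero (no
  spurious residual signal), and the feature carrying the dominant
  coefficient (HP) ranks first in stage-1 importance. Two identifiability
  points shaped this scenario. First, with only 3 wetlands every
  per-wetland attribute encodes the same 3-level partition, so impurity
  importance is arbitrarily split among perfectly collinear features;
  the attribution scenario therefore uses 12 wetlands with independently
  drawn land-use mixes (including HP drawn independently of the
  size-ordered morphometrics). Second, any generative component that is
  synchronised with the seasons but carries no β — the quarter sinusoid,
  or vegetation seasonality reaching concentrations through γ — is
  proxied by the strongly seasonal temperature covariate, which then
  legitimately outranks HP; isolating the discrete pathway removes that
  confound so the test asks only whether importance ranks the dominant
  coefficient first.
* **Determinism.** All stochastic steps (field generation, noise, the
  split, both forests) are seeded; forests run single-threaded with
  ranger's `seed` argument, so a fixed configuration reproduces metrics
  byte for byte.

## Numerical and interface choices

* Every elementwise division is guarded: zero denominators become nodata,
  never infinities. Nodata is an explicit mask on every band, serialised
  as the format's nodata tag.
* Rasters are serialised as ESRI ASCII grids (a plain-text raster
  interchange format carrying georeferencing in its header) grouped in
  scene directories with a JSON manifest for date, sensor, per-band units
  and the CRS label; wetlands travel as GeoJSON, samples and climate as
  CSV with ISO-8601 dates; feature tables get a JSON schema sidecar
  recording feature order and units.
* Polygon area/perimeter use the planar shoelace formula (map units are
  metres). Simplicity is checked in O(n) for rings that wind monotonically
  about their centroid, with an exhaustive crossing test for small
  non-star rings. SCI is scale-dependent (km per km²) by definition and
  is documented as such.
* Random-forest defaults: 500 trees, mtry = ⌊p/3⌋, unlimited depth,
  minimum node size 1, impurity importance (permutation available); all
  exposed through `rf_params()`.
* Reflectances are assumed scaled to [0, 1]; integer-scaled inputs should
  be divided by their quantification value (e.g. 10000) on ingest.
* Negative final concentrations are clipped to 0 by default (a physical
  bound); the unclipped value is retained in a diagnostic layer
  (`final_raw`).
* The pipeline's function surface (`run_config()`, `run_pipeline()`,
  plus the generator and fitting functions) is the primary interface; a
  thin command-line wrapper with `synth` and `run` subcommands ships in
  `inst/cli/wetstage.R` for shell use. Each pipeline output embeds a
  deterministic configuration hash, and a JSON-lines log records
  per-stage row counts and seeds.

## Problem sizes used in the shipped validation

The package's own test suite fits models on studies of two sizes, chosen
as the smallest that still exercise every code path meaningfully: the
full default study (3 wetlands, 324 samples, 200 × 200 grid, 36 months)
for end-to-end recovery, map algebra, and the acceptance script; and a
reduced study (48 × 48 grid, 6 months, 54 samples) for pipeline plumbing
and serialization tests. Replicate loops use 20 seeds. A single default
study generates, composites, and fits in well under two minutes on one
CPU.

## Known limitations

* The additive two-stage decomposition cannot express interactions
  between landscape and pixel scales, and stage 2 sees only surface
  conditions — subsurface processes are invisible to it.
* Quarterly compositing suppresses short-lived events (storm pulses);
  monthly compositing would trade noise for temporal resolution.
* With few wetland units, per-feature attribution of stage-1 importance
  across collinear landscape attributes is not identifiable (see
  *Validation design*); interpret stage-1 rankings at that scale as
  identifying the wetland-level signal, not a specific attribute.
* No reprojection, cloud masking, orbit bookkeeping, or uncertainty
  quantification; kriging of residuals and spatial cross-validation are
  out of scope.
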