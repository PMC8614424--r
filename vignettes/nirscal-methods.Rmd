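---
title: "Methods: NIRS calibration with modified PLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NIRS calibration with modified PLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirscal)
```

## The problem

Near-infrared reflectance spectroscopy estimates the chemical composition
of ground forage from its absorbance spectrum, `log(1/R)` over 850–2500 nm.
A calibration model is regressed from spectra against laboratory reference
values (% of dry matter) for moisture, crude protein (CP), neutral and acid
detergent fiber (NDF, ADF), acid detergent lignin (ADL), and hemicellulose,
which is defined as the difference NDF − ADF. The workflow this package
implements is the conventional one for straw and forage calibrations:
replicate-scan averaging, spectral outlier screening, a rank-stratified
calibration/validation split, a grid search over spectral pretreatments,
modified-PLS regression with cross-validated factor selection and
compositional outlier removal, then external validation and quality
classification.

## Modified partial least squares

The regression core is PLS1 fitted by NIPALS deflation. Writing `X` for
mean-centered spectra and `y` for the centered response, each factor
extracts a weight vector `w ∝ X'y`, scores `t = Xw`, loadings
`p = X't/t't`, `q = y't/t't`, and deflates `X ← X − tp'`, `y ← y − qt`.
The *modification*: after each factor, the spectral residuals at each
wavelength are divided by their standard deviation before the next factor
is computed. The per-factor scale vectors are stored in the model and
replayed at prediction time, so prediction is an exact linear map; the
composed coefficient vector is computed by reverse accumulation through
the deflate-then-scale recursion. With standardization off the procedure
is exactly PLS1, which the tests exploit: the unmodified path is checked
against an independent formulation (k-factor PLS1 fitted values are the
least-squares projection of `y` onto the Krylov space spanned by
`(X'X)^j X'y`, `j < k`), and at full rank against ordinary least squares.

The residual SDs are floored at `1e-12` before division so perfectly
fitted wavelengths cannot blow up the scale replay. The MPLS residual
standardization re-weights wavelengths relative to plain PLS1 from the
second factor on; the first-factor weights of the two procedures are
identical by construction.

### Factor selection

Cross-validation assigns samples to `groups = 4` folds by a seeded shuffle
followed by round-robin allocation — a shuffle, not consecutive blocks,
because calibration sets sorted by reference value would otherwise
confound folds with concentration. `SECV(k) = sqrt(Σe_cv²/n)` is computed
for every factor count up to `max_factors = 16`, and the chosen count is
the *smallest* `k` with `SECV(k) ≤ 1.02 × min SECV`. The 2% parsimony
tolerance (configurable) avoids the overfitting of factor count that a
strict argmin shows on small calibration sets; four groups and sixteen
factors are the conventional defaults for data sets of one to a few
hundred samples.

## Pretreatments

A pretreatment pairs a scatter correction with a math treatment and is
serialized as e.g. `"1,4,4,1+SNV"`. The math treatment numerals follow the
WinISI convention — derivative order, gap in data points, first
running-average width, secondary smoothing width — and are implemented as:
boxcar of width `s1`, then a symmetric gap difference (order 1:
`y(i+h) − y(i−h)`, `h = ⌈gap/2⌉`; order 2: `y(i+g) − 2y(i) + y(i−g)`,
`g = gap`), then a boxcar of width `s2`. Gap counts index data points, not
nm. Savitzky–Golay filtering is deliberately not used: the gap-segment
convention is what the 4-numeral notation describes. Edges are trimmed,
never padded; the transformed set carries its trimmed wavelength grid so
downstream dimensions are honest. `0,0,1,1` is the identity.

Scatter corrections: SNV (per-spectrum standardization, population SD);
detrend (2nd-degree polynomial baseline removal, the conventional degree);
SNV + detrend; standard and weighted MSC (regression of each spectrum on
the calibration-set mean, corrected as `(x − a)/b`); and mean-scaling
followed by polynomial detrend of degree 1 or 2 (the reading adopted for
the "scale + linear/quadratic" pretreatment labels, which have no public
definition; it is configurable). Weighted-MSC weights are the inverse
residual variance about the mean spectrum, floored at `eps = 1e-10` —
also an interpretation, flagged as such, since no public definition
exists. MSC state (mean spectrum, weights) is fitted on calibration
samples only and reused unchanged for validation samples.

Order of operations: scatter correction first, then the math treatment.
The pairing of the two is reported jointly in the source material without
an order; the conventional order (corrections act on `log(1/R)`, not on
derivative spectra) is fixed here and applied consistently to calibration
and validation sets.

## Outlier screening

**Spectral** (before splitting): PCA on centered spectra; the smallest
number of components explaining ≥ 99% of variance (capped at 20) is
retained; `GH_i = Σ_k (score_ik/SD_k)²/K` is the Mahalanobis distance in
score space per component, so the fitting-set mean is ≈ 1. Samples with
`GH > 3` are discarded. Threshold, variance fraction and cap are config
keys; the values are standard practice.

**Compositional** (during calibration): cross-validate, remove samples
with `|ŷ_cv − y| > 3 × SECV`, refit; at most 2 passes by default. The
kept set only shrinks; under Gaussian residuals the expected removal
fraction is well under 1% (checked by simulation at n = 500). Screening
runs independently per constituent, which is why reported calibration
counts differ between constituents.

## Split and grid search

Samples are sorted by reference value; within each block of `fold = 5`
the sample at `offset = fold %/% 2` goes to validation. The middle offset
keeps the extreme minimum/maximum values in the calibration set, so the
validation range lies inside the calibration range. Splitting is
per-constituent, consistent with per-constituent screening.

The default grid crosses five math treatments
`{(0,0,1,1), (1,4,4,1), (2,4,4,1), (1,8,8,1), (2,8,8,1)}` with six scatter
corrections `{none, SNV, detrend, MSC, weighted MSC, scale+linear}` — 30
candidates. Candidates are ranked by `1-VR` descending with SECV ascending
on ties: both are cross-validated and therefore honest, whereas SEC and
`RSQ_C` are in-sample; the four-way "low SEC/SECV, high RSQ_C/1-VR"
selection idiom collapses to this single honest key (configurable). A
candidate whose window exceeds the spectrum is recorded as failed, not
fatal. `scale+quadratic` is implemented and can be added to the grid via
config; the default grid keeps the 5 × 6 = 30 layout.

## Statistics and classification

With `e = ŷ − y` (bias is predicted minus reference):
`SEC = sqrt(Σe²/(n−1−k))` on the calibration fit (factors consume degrees
of freedom), `SECV = sqrt(Σe_cv²/n)`, `RSQ_C = 1 − Σe²/Σ(y−ȳ)²`,
`1-VR = 1 − Σe_cv²/Σ(y−ȳ)²`; on validation, `bias = mean(e)`,
`SEP = sqrt(Σe²/n)`, `SEP(C) = sqrt(Σ(e−bias)²/(n−1))`, slope of the
regression of laboratory value on prediction, `RSQ_V = cor(y, ŷ)²`, and
`RPD = SD_val/SEP`. The divisor conventions are stated at each formula
site; they satisfy the identity `SEP² = bias² + SEP(C)²·(n−1)/n`, which is
asserted in the tests. CV is `100·SD/mean` to 2 decimals.

Quality bands combine both thresholds with AND, inclusive lower bounds,
best band first: excellent (RSQ ≥ 0.95, RPD ≥ 4.0), successful
(0.90/3.0), moderately successful (0.80/2.25), moderately useful
(0.70/1.75), otherwise screening only. Published usage is ambiguous about
whether the calibration or validation R² enters the classification, so
`classify_model(rsq, rpd)` takes it explicitly and the pipeline reports
which one was used (`classify_on`, default `rsq_c`).

## The synthetic-data generator

No spectra were deposited for the straw study this workflow targets, so
the package generates data with the statistical structure the analysis
assumes.

**Compositions.** Moisture, CP, ADF, ADL and hemicellulose are sampled
from truncated normals whose truncated-distribution moments match the
published per-species means and SDs (bounds = published min/max). The
moment matching matters: corn ADL has bounds [1.17, 10.70] around a mean
of 3.26, and naively truncating an N(3.26, 1.61²) would shift the mean by
about +0.3. NDF is set exactly to ADF + hemicellulose, so the fiber
identity holds in synthetic truth, and ADL ≤ ADF is enforced by redraw.
Default profiles encode the published corn-stover and wheat-straw
calibration statistics (e.g. corn CP mean 5.18, SD 1.34 % DM).

**Spectra.** Beer–Lambert mixing: each constituent has an absorptivity
curve, a positive sum of Gaussian bands on the grid, and the clean
spectrum is the concentration-weighted sum. Band centers are chemically
motivated and mutually distinct per constituent (water O–H 1450/1940 nm;
protein 1510/2055/2180 nm; cell-wall carbohydrate 1730/2100/2345 nm;
cellulose 1490/2110/2450 nm; lignin 1685/2270/2440 nm; xylan
2090/1925/2460 nm), keeping the mixture problem well conditioned while
the *average* spectrum shows the five main straw absorption peaks near
1450, 1900, 2100, 2300 and 2450 nm. The fifth peak is placed at 2450
rather than the scan edge at 2500 nm so its full Gaussian fits inside the
grid. Scatter is applied per sample: multiplicative factor
`b ~ N(1, 0.1)`, additive offset `a ~ N(0, 0.05)`, linear tilt
`t ~ N(0, 0.02)` across the range, plus iid Gaussian noise with SD 0.002
absorbance units. These magnitudes are package constants changed only by
configuration, never inside stages.

All randomness flows from one profile seed through named, counter-indexed
substreams (one per sample per operation), so drawing `n + k` samples
reproduces the first `n` exactly, and the pipeline's master seed fans out
to independent substreams for simulation, cross-validation and screening.

**What it does and does not emulate.** The generator reproduces additive
constituent absorptions, multiplicative/offset/tilt scatter of the kind
the corrections target, composition ranges and between-species mean
shifts. It does not model instrument line shape, wavelength-dependent
path length, temperature or moisture-exchange effects, band shifts with
hydrogen bonding, or non-linear detector response. Passing tests on
synthetic data therefore demonstrate the *statistical machinery* —
recovery, screening, selection, honest cross-validation — not instrument
transferability. One structural consequence: because the simulated
multiplicative scatter also scales the constituent signal, any scatter
correction that removes it also removes absolute-concentration scale, so
cross-validated errors plateau at a floor set by the scatter magnitude
rather than the noise floor; this mirrors the real phenomenon that
path-length variation limits NIRS accuracy.

**Default grid.** The simulator works on 850–2500 nm at a 2 nm step (826
points) rather than the instrument's 0.5 nm (3301 points): the synthetic
bands are ≥ 35 nm wide, so 2 nm sampling changes none of the statistics
while keeping full-pipeline runs fast; the 0.5 nm grid is available via
`grid_step = 0.5`.

## Numerical choices and degenerate inputs

- Wavelength grids must be uniform to 1e-9 nm; grid mismatches are errors,
  never silently interpolated.
- SNV of a constant row, MSC slope below 1e-12, zero-mean rows in
  mean-scaling, zero-variance responses, and all-samples-flagged screens
  are errors, not silent results.
- Rank exhaustion during factor extraction truncates with a warning.
- Ties in the rank-stratified sort are broken by sample id; grid-search
  ties beyond (1-VR, SECV) are broken by the pretreatment string, so all
  orderings are total and deterministic.
- Model JSON serialization writes doubles through `%.17g` strings so
  reloaded models predict bit-identically.

## Problem sizes

The test suite runs reduced configurations (40–200 samples, 8 nm grids,
2–4 pretreatment grids) chosen so each contract is exercised in seconds;
the acceptance script runs the full default study — 120 samples per
species, 826-point grid, the 30-cell pretreatment grid, all six
constituents, per-species plus combined workflows — in a few minutes on
one CPU.

## Known limitations

- The MPLS deflation/scaling order follows the verbal description of the
  algorithm (deflate, then standardize, replayed at prediction); the
  commercial implementation is proprietary and may differ in detail.
- "Scale + linear/quadratic" and weighted-MSC weights are documented
  interpretations (see above), both configurable.
- PLS2 (multi-response), uncertainty intervals, wavelength selection,
  robust PCA variants and reflectance-to-absorbance conversion are out of
  scope.
- Instrument binary formats are not parsed; the native format is
  delimited text.

## A minimal run

```{r example, eval = FALSE}
cfg <- run_config(seed = 1, constituents = "cp")
out <- run_combined_workflow(cfg)
out$comparison
```
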