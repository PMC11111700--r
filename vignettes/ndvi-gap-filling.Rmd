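---
title: "Gap-free daily NDVI reconstruction: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gap-free daily NDVI reconstruction: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(vigapfill)
```

## The problem

Daily NDVI records assembled from AVHRR/VIIRS-class sensors are riddled with
two kinds of defects: *gaps* (orbital coverage, sensor outages, month-scale
blackouts around satellite replacements) and *contamination* (cloud and
aerosol effects that mostly bias NDVI downward, plus sporadic positive
outliers). Smoothing or interpolating such a series without first deciding
which observations to trust propagates the contamination into the result.
`vigapfill` therefore separates the two concerns: a screening stage labels
every daily observation of every pixel as valid, invalid or missing, and a
reconstruction stage fits a smooth seasonal trajectory to the surviving
valid data only, filling every day of the record.

## Valid-data identification

Screening works per pixel on a three-month sliding window (one window per
target calendar month).

**Stage 1 (day level, threshold `t1`).** For the target month the screen
collects the monthly maxima of the previous, target and next months —
monthly maxima because cloud contamination is negatively biased, so the
within-month maximum is the most trustworthy summary of the local greenness
level — and augments them with the means of (previous, target) and (target,
next). That yields up to five reference values per window. A daily value `v`
is valid when its absolute percent bias `|v - ref| / ref * 100` to **at
least one** reference is within `t1`. The five references cover the
plausible levels a clean observation can take inside a month: early days
resemble the previous month's level, late days the next month's, mid-month
days the month's own maximum.

**Stage 2 (month level, threshold `t2`).** A whole pixel-month is
invalidated when it contains no data at all, or when the percent bias
between its maximum and the mean maximum of the same calendar month in the
two preceding and two following years exceeds `t2`. This catches months so
pervasively contaminated that stage 1's own references are corrupt.

The defaults `t1 = 20` and `t2 = 39` (percent) follow the calibration
procedure implemented in `calibrate_thresholds()`: applied to a multi-decade
monthly-maximum reference series, `t1` is the mean absolute percent bias
between adjacent-month maxima, and `t2` the mean over pixels of the
per-pixel maximum of that quantity. On long AVHRR-era reference data these
statistics come out near 20% and 39%.

Interpretation choices the published description leaves open, and how this
package resolves them:

* *"at least one" vs "all" references within `t1`* — the default is
  at-least-one (validity means proximity to **some** plausible local level);
  requiring all references would reject nearly every observation in months
  whose neighbours differ by more than `t1`, e.g. during green-up. The
  strict reading remains available via
  `identification_config(semantics = "all")`.
* *Window truncation* — at record edges the window simply loses the absent
  neighbour month (3-member reference set instead of 5) rather than
  discarding the first and last months.
* *Neighbour years* — years y−2, y−1, y+1, y+2, truncated at record edges;
  when no neighbour month has data the interannual test is skipped.
* *Stage-2 inputs* — monthly maxima are computed from the **raw**
  non-missing data, not from stage-1 survivors, keeping the two screens
  independent. See Limitations for the consequence in short records.
* *Zero references* — percent bias against a zero reference is undefined;
  such references are skipped, and a day whose references are all zero is
  classified invalid.

## Segmented quartic reconstruction

Greenness trajectories are asymmetric between green-up and senescence, so
each pixel-year is reconstructed from two separate least-squares quartic
fits split at the **peak**: the date of the year's maximum valid value
(earliest date on ties).

* the *growth* segment pools valid data from October–December of the
  previous year and January up to the peak;
* the *withering* segment pools the days after the peak through December
  plus January–March of the following year.

Carrying three months of context across the year boundary anchors the fits
at the winter level and prevents end-of-year extrapolation artifacts. Days
January 1 to the peak are evaluated from the growth polynomial, days after
the peak from the withering polynomial.

Numerical choices:

* Each segment's time axis is affinely rescaled to [−1, 1] over its window
  before fitting (a raw Vandermonde in days spanning ~270–450 days is badly
  conditioned at degree 4); origin and scale are stored with the
  coefficients so evaluation is exact.
* A segment is fitted only with at least `min_points = 10` valid
  observations on at least 5 distinct dates. Five points make a quartic
  identifiable; ten guard against wild extrapolation from clustered data.
  Below that the segment *falls back* and its days are left for the
  adjacent-year fill — mirroring the method's own residual-fill mechanism
  rather than silently reducing the polynomial degree.
* Outputs are clamped to [−1, 1], the physical NDVI range.
* Fitted values replace **all** days, including originally valid
  observations (`keep_observations = FALSE`). This is what makes
  self-validation against the original valid data meaningful: the published
  accuracy of the approach (overall R² about 0.79 against original valid
  observations) is only possible if valid days are themselves re-estimated.
  Setting `keep_observations = TRUE` passes valid observations through.
* No continuity constraint ties the two fits at the peak; the mean absolute
  discontinuity is logged per pixel in the `fit_stats` attribute so users
  can inspect it.

**Residual fill.** Whatever the fits could not cover (fallback segments,
years with no valid data at all) is filled by the mean of the reconstructed
values on the same calendar day in years y±1 and y±2, with February 29
mapping to February 28 in non-leap neighbours. Only fit-stage values act as
donors, so the result is independent of the order in which gaps are
visited. A gap with no donor in any of the four neighbour years is a hard
error rather than a silent hole — the gap-free guarantee is never faked.

## Evaluation

`pixelwise_metrics()` computes the five standard criteria per pixel —
Pearson r, R² = 1 − SSres/SStot (residuals about the comparison series'
mean), MAE, RMSE and percent bias PB = mean((rec − ref)/ref) × 100. In
self-validation mode only days the mask labels valid enter the comparison;
dataset inter-comparison uses all paired days. `quality_classification()`
applies the two standard rules: high quality against the source data means
|PB| < 1%, RMSE < 0.08 and R² > 0.5 simultaneously; consistency with an
independent daily product means r > 0.5, |PB| < 50% and RMSE < 0.2. Area
proportions are plain pixel shares (no cos-latitude weighting — the
published proportions are reported on the 0.05° grid without weighting),
and latitudinal profiles aggregate one grid row per band. Monthly
maximum-value composites (`mvc_monthly_composite()`) and nearest-neighbour
regridding (`regrid_nearest()`, ties to the smaller index) support
comparisons against monthly products on other grids.

## The synthetic scene generator

Real multi-decade archives cannot ship with a package, so the generator
builds scenes with known truth:

* **Truth** is a per-pixel double-logistic annual curve — winter base 0.12,
  amplitude 0.55, green-up day 120, senescence day 280, rates 0.09 and 0.07
  per day, 4% interannual jitter, with a mild deterministic spatial gradient
  — a standard mid-latitude phenology shape. A double logistic, not a
  quartic, so recovery tests do not favour the quartic fitter.
* **Contamination** applies, in order: whole-scene transition gaps (the
  default scene has one 30-day gap starting 2002-06-01, emulating a
  satellite-replacement outage), 50% random dropout, cloud depression on 20%
  of remaining days (multiplicative factors 0.3–0.7, i.e. negatively
  biased), and 1% positive spikes (additive 0.1–0.4, clamped at 1). Every
  cell's fate is recorded in a ledger, so `score_identification()` can
  compute the precision and recall of the screening exactly.
* A separate quartic-truth generator (`simulate_quartic_truth()`) backs the
  exactness tests: one smooth quartic per pixel across the whole record, so
  every growth/withering segment sees data from a single quartic and the
  reconstruction must reproduce it to numerical precision. Shapes whose
  annual peak falls unresolvably close to the record edge (within 20 days of
  the first year's start, or of the last year's end short of the final day)
  are redrawn, since no segment-based method can fit a sliver shorter than
  its minimum support.

The default test scene is 20 × 20 pixels × 3 years (2001–2003) — small
enough that the full pipeline runs in seconds, large enough for stable
medians over pixels. What the synthetic scenes do **not** emulate: spatially
correlated cloud fields, sensor drift and BRDF artifacts, mixed land-cover
phenologies, and snow. Passing recovery tests on these scenes demonstrates
the mechanics of the method (screening fidelity, segment fitting, gap-free
output), not its accuracy on real archives.

## Worked example

```{r pipeline, eval = FALSE}
scene <- demo_scene(seed = 1)
mask  <- identify_valid(scene$observed)
recon <- reconstruct_cube(scene$observed, mask)

missing_count(recon)                               # 0: gap-free
score_identification(mask, scene)                  # screening vs ledger
mm <- pixelwise_metrics(recon, scene$truth)
median(mm$r2[!mm$flag])                            # recovery of the truth
```

On the default scene this yields a gap-free cube, contamination recall near
0.88, and a median per-pixel R² against the hidden truth near 0.96 (values
computed by `scripts/acceptance.R`, which re-runs exactly this pipeline).

## Known limitations

* **Spike poisoning of the month screen in short records.** Stage 2
  compares raw monthly maxima across years. A single positive spike inflates
  one month's maximum; in a 3-year scene each month has at most two
  neighbour years, so that one spiked month can push the interannual percent
  bias of the *same calendar month in its neighbour years* past `t2`,
  invalidating their clean days as collateral. This caps screening
  *precision* near 0.6 on the default scene (recall is unaffected), and is
  most visible in winter months where a spike is a large relative excursion.
  In a multi-decade record the four-neighbour mean dilutes single spiked
  months and the effect largely vanishes. Computing stage-2 maxima from
  stage-1 survivors would remove it entirely, but would couple the two
  screens; this package keeps them independent, as the framework describes.
* Fast green-up/senescence months can see clean early- or late-month days
  rejected by stage 1 when they sit more than `t1` below every reference —
  the known cost of a fixed percent-bias threshold.
* The quartic is a smoother, not a phenology model: double or multi-modal
  growing seasons within one calendar year are fitted by a single peak
  split and may be flattened.
* Reconstruction quality at the first and last year of a record relies on
  truncated segments (no previous October–December, or no following
  January–March).
* No uncertainty is propagated; the output is a point estimate.
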