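---
title: "Methods: Fishing Season Indices and Neural-Network Fishing Zones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Fishing Season Indices and Neural-Network Fishing Zones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandapfz)
```

`bandapfz` implements a two-part analysis of a small pelagic fishery:
a seasonal decomposition of catch rates (the Fishing Season Index) and a
neural-network habitat model that maps potential fishing zones from
satellite oceanography.  This vignette documents the methods, the
numerical choices behind them, what the synthetic-data generator does
and does not emulate, and the known limitations.

## Catch-rate standardization

Raw landings confound abundance with effort, so everything downstream
works on catch per unit effort, `CPUE = Catch / Effort` in kg per trip.
Monthly aggregation pools catch and trips *before* dividing
(`Σcatch / Σtrips`), which weights each trip equally rather than each
landing — the standard treatment for trip-level records.  A month inside
the observed span with no records is an error, never a silent zero: a
zero would masquerade as a collapsed fishery and corrupt the moving
averages.

## The Fishing Season Index

The FSI is a classic ratio-to-moving-average seasonal index.  For a
monthly series `CPUE_1..n` (n ≥ 24, two full seasonal cycles):

* `MA_i = mean(CPUE_{i-6} .. CPUE_{i+5})` — a 12-month moving average,
  defined where the window fits (indices 7..n−5).
* `CMA_i = (MA_i + MA_{i+1}) / 2` — the centered moving average.  An
  even-length window cannot be centered on a month, so two adjacent
  window means are averaged; this is the textbook construction, and the
  one this package uses.
* `AM_i = CPUE_i / CMA_i` — the seasonal ratio, the month's catch rate
  relative to its local trend.
* `AAM_m` — the mean of month *m*'s ratios over the years that have one.
  Edge months whose window does not fit contribute nothing: a 60-month
  series has ratios on indices 7..54, so each calendar month averages
  exactly 4 ratios, not 5.  The per-month count is carried in the result
  (`n_ratios`) rather than assumed.
* `TAM = Σ AAM`, `CF = 1200 / TAM`, `FSI_m = AAM_m × CF` — the
  correction factor forces the twelve indices to sum to 1200, so FSI
  reads as a percentage of an average month.  `ΣFSI = 1200` is enforced
  to 1e-6 relative in the tests; it holds by construction for any valid
  series, and the published 2019–2023 western Banda Sea season table that
  ships as a fixture sums to 1199.999, i.e. 1200 within printing
  precision.

Two numerical guards matter.  A centered average at or below
`1e-9 × mean(CPUE)` leaves the ratio undefined (with a warning) instead
of dividing by a near-zero trend; and the reported dispersion
(`std_dev`) is the sample (n−1) standard deviation of each month's
CF-scaled ratios, so it shares the FSI's percent units.  The dispersion
column of the published table is consistent in magnitude with this
reading, but the original computation is not described; it is an
interpretation, and it is labelled as such here.

### Season classification

The month with the maximum FSI is the **peak season**; other months are
**fishing seasons** at FSI ≥ 100 (above an average month), **lean
seasons** below 30, and **regular seasons** between.  The fishing
boundary at 100 is canonical (the indices average 100 by construction).
The lean boundary is not: published usage for this fishery separates a
19.7 lean month from a 34.3 regular month, so any cut in (19.7, 34.3]
reproduces the published labels.  30 was chosen as a round value
comfortably inside that interval, and the threshold is configurable
(`season_thresholds()`).  A tied maximum labels every tied month peak,
with a warning — a constant series is all-peak, which is the honest
degenerate answer.

## The habitat model

The regression network is deliberately small: four environmental inputs
(SST, CHL-a, SSS, current speed), one hidden layer of 10 sigmoid
neurons, one linear output for CPUE.  Ten hidden units is the width
found adequate by trial and error for this problem size and is the
package default; it is exposed in `network_spec()`.

Inputs and target are min-max scaled to [0, 1] on the *training* rows —
sigmoid layers condition poorly on raw oceanographic scales (psu ~34,
kg/trip ~300).  The scaling lives inside the fitted model, so prediction
accepts raw units and returns kg/trip, and predictions are invariant to
affine rescaling of any input column (refitting included), which the
tests assert.

Data are split 70/30 by seeded random sampling into disjoint, exhaustive
train and test sets.  Weights start Xavier-uniform from the same seed,
so a (data, seed, config) triple reproduces the model bit for bit.

### Optimizer

Gradients are exact backpropagation through the scaled-space batch MSE,
verified against central finite differences to better than 1e-5 relative
error on random networks.  Two full-batch optimizers are provided:

* **iRprop⁻ (default).**  Resilient backpropagation: each parameter
  carries its own step size, grown ×1.2 while its gradient keeps sign
  and halved on a sign flip (the flipped step is suppressed).  This is
  the classic full-batch training rule for sigmoid networks, and the
  difference is not cosmetic here: on noiseless synthetic data plain
  gradient descent at rate 0.01 reaches predicted-vs-true R² ≈ 0.95
  after 5000 epochs, while iRprop⁻ reaches ≈ 0.999 in the same budget.
* **Plain gradient descent (`optimizer = "gd"`).**  A single global rate
  with backtracking: a step that would raise the training loss is
  retried at half the rate, so the accepted-step loss sequence is
  non-increasing.  Kept for its transparency and as a reference.

Early stopping watches the held-out MSE (`patience` accepted epochs
without improvement) and the returned model is the best held-out state
seen, not the last.  For convergence studies set
`patience = max_epochs`: on this problem the held-out MSE plateaus long
before the fit at low-CPUE cells has finished improving, so an
aggressive patience can stop early with a visibly worse relative error.

### Error metrics

`evaluate_predictions()` reports MSE, RMSE = √MSE (an identity the tests
check at 1e-12), the mean absolute percentage error over nonzero actuals
(`error_rate_percent`), and the range-normalized RMSE
(`nrmse_percent`).  Both percentage metrics are reported deliberately.
A multiplicative observation noise of CV c contributes roughly
`c·√(2/π)` to MAPE no matter how good the model is — about 4% at c =
0.05 and 28% at the generator's default 0.35 — and relative error
concentrates at low-CPUE observations, so trip-level MAPE is a blunt
instrument for model quality.  Range-normalized RMSE is not noise-floor
limited in the same way; error rates of order 1% reported for comparable
catch-rate models are plausible only under a range-normalized reading.
The package's own measured figures at 5% noise (recomputed by the test
suite and the acceptance script, 6000-epoch budget) are NRMSE ≈ 2.5–2.7%
and MAPE ≈ 6–12% across seeds; the tests assert NRMSE < 5% per seed and
MAPE < 15% as a sanity bound.

## Predictor contributions

Two estimators, clearly labelled, neither claimed to reproduce any
externally published percentage:

* **Permutation importance (default).**  Mean increase in held-out MSE
  over seeded within-column shuffles (100 repeats by default), negatives
  clipped to zero, normalized to percent.  Model-agnostic and tied to
  realized predictive skill.
* **Connection weights.**  A Garson-style partition of
  `|input→hidden| × |hidden→output|` weight products, normalized to
  percent.  Structural, cheap, but a cruder proxy: on noiseless fits it
  concurs with permutation importance on the dominant predictor in most
  seeded runs, not all, occasionally swapping the top two.  This
  unreliability of weight-based saliency is well documented and is why
  permutation importance is the default.

## Potential fishing zones

`predict_grid()` applies the fitted network cellwise to one month's four
grids (which must share shape and coordinates) and flags the PFZ as the
cells in the top decile of predicted CPUE.  The mask keeps the
`k = ⌈(1−q)·n⌉` largest predictions; ties at the threshold enlarge it,
so a constant prediction degenerates to "everywhere", which is reported
rather than hidden.  The threshold choice (quantile 0.9) has no
published definition to follow; the top decile is a conventional
hotspot cut and is configurable.

`locate_maximum()` reports the argmax cell and the four environmental
values at that exact cell (asserted identical to the input grids, never
interpolated).  Ties resolve deterministically to the first cell in
storage order (latitude varying fastest within longitude) with a
warning.  Latitude is stored signed (south negative); grids are
cell-center registered; current speed is cm/s throughout, with
`current_to_cms()` for m/s sources, since satellite current products and
the regional catch-rate literature mix the two units.

Maps export as long CSV or as ESRI ASCII grid — a plain-text
georeferenced raster whose header encodes the study box corner
(120°E, 5°S) and cell size, readable by standard GIS tools.

## The synthetic generator

`generator_config()` defines the study conditions: a 0.25° grid over
120–126°E, 2–5°S, 60 monthly steps from January 2019, and four fields
built as *spatial gradient + 12-month sinusoid + seeded Gaussian noise*,
clamped to physical bounds.  The seasonal phases put the CHL-a, current
and salinity peaks in the monsoon-transition months (October–November),
when upwelling raises productivity in this system; salinity stays inside
the 30–34.2 psu envelope observed there.

Expected CPUE is a known function of the four predictors: Gaussian
suitability terms peaked at SST 31.4 °C, SSS 34.2 psu, current
3.29 cm/s, a flat band at CHL-a 0.18–1.5 mg/m³, raised to
salinity-dominant weights (sss 2.0 > current 1.2 > sst 0.8 > chl 0.6)
and scaled to a 343 kg/trip maximum.  Field means are set so each
predictor's realized monthly swing actually exercises its suitability
term — the current field averages 2.2 cm/s and peaks near its 3.29 cm/s
optimum in November — because a predictor whose field never leaves its
optimum has no realized effect, whatever its weight.  With these
defaults the monthly CPUE series spans roughly 8–310 kg/trip (a ~30×
seasonal range, matching the scale of published monthly means for this
fishery) and permutation importance recovers the sss > current ordering
in ≥ 90% of seeded runs, which the acceptance checks assert.

Catch records follow fisher behaviour in shape: cells are sampled with
probability proportional to the true response (effort concentrates on
good habitat), trip counts are 1 + Poisson, and catch is
`trips × response × lognormal noise` with mean 1 and CV `noise_cv`
(default 0.35, a realistic trip-level spread; 0 gives exact recovery of
the response, which the tests exploit).  About 280 trips per month are
generated, ~16.8k over five years.

What the generator does **not** emulate — and hence what passing tests
do not demonstrate about real data: spatially or temporally correlated
observation noise; interannual variability (ENSO, trend); lagged
environmental effects (e.g. CHL-a leading catches by a month); vessel
heterogeneity and preferential sampling beyond the response weighting;
cloud gaps and retrieval error in satellite fields.  Parameter-recovery
results here certify the pipeline's correctness, not the ecological
model of any real fishery.

## Problem sizes and reproducibility

Tests run the generator at reduced sizes (0.5° grids, 24–36 months,
60 trips/month) except where the check is about the default conditions
(the importance-recovery and error-rate properties use the full 60-month
default).  Training budgets in tests are 600–6000 epochs depending on
how converged a model the property needs.  Every stochastic step —
field noise, catch sampling, the 70/30 split, weight init, permutation
shuffles — derives from explicit seeds, and stage seeds are derived from
the single global seed so that runs are reproducible end to end;
`scripts/acceptance.R --seed N` re-derives everything from one integer.

## Known limitations

* The hidden layer is a single sigmoid block; no regularization or
  architecture search is attempted beyond the configurable width.
* Permutation importance on correlated predictors (the seasonal cycles
  co-vary by construction) splits credit between proxies; the reported
  percentages are conditional on this design, not causal shares.
* Connection-weight contributions can misrank predictors of similar
  strength (see above).
* The FSI assumes a stable 12-month seasonality; series shorter than 24
  months are rejected rather than extrapolated, and trend changes within
  the window bleed into the ratios.
* Current speed magnitudes follow the regional catch-rate literature
  (single-digit cm/s); other current products may need unit conversion
  and plausibility checks before use.
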