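# bandapfz

Seasonal analysis and habitat-based prediction of small pelagic catch
rates, built around the Indian mackerel (*Rastrelliger* spp.) purse-seine
fishery of the western Banda Sea (120–126°E, 2–5°S).

Fisheries scientists working with landings data and satellite
oceanography face two recurring questions: *when* is the fishing season,
and *where* are the productive grounds?  `bandapfz` answers both from the
same inputs — trip-level catch records and monthly gridded fields of sea
surface temperature (SST, °C), chlorophyll-a (CHL-a, mg/m³), sea surface
salinity (SSS, psu) and surface current speed (cm/s):

1. **CPUE standardization.** Catch is standardized to catch per unit
   effort, `CPUE = Catch / Effort` (kg/trip), pooled by month.
2. **Fishing Season Index (FSI).** A ratio-to-moving-average seasonal
   decomposition: a 12-month moving average `MA_i = mean(CPUE_{i-6..i+5})`
   removes trend, the centered average `CMA_i = (MA_i + MA_{i+1})/2`
   aligns it on month *i*, the ratios `AM_i = CPUE_i / CMA_i` are averaged
   per calendar month into `AAM_m`, and the correction factor
   `CF = 1200 / Σ AAM` rescales them so the twelve indices `FSI_m =
   AAM_m × CF` sum to exactly 1200 (mean 100).  Months are then classed
   as peak (the maximum), fishing (FSI ≥ 100), lean (FSI < 30) or
   regular seasons.
3. **Backpropagation network.** A from-scratch feed-forward regressor
   (4 inputs → 10 sigmoid hidden neurons → 1 linear output) is trained by
   full-batch backpropagation on min-max-scaled data, with a seeded 70/30
   random train/test split and MSE/RMSE evaluation.
4. **Predictor contributions.** Permutation importance (mean increase in
   held-out MSE under column shuffles) and a connection-weight partition
   of the trained network, both normalized to percent.
5. **Potential fishing zones (PFZ).** The trained network is applied
   cellwise to monthly environmental grids; the top decile of predicted
   CPUE delineates the PFZ, and a hotspot report gives the maximum and
   the environmental conditions at that cell.

A seeded synthetic-data generator emulates the study system — monsoon-
cycled environmental fields over a 0.25° grid and a catch process whose
expected CPUE is a known function of the four predictors (peaked at SST
31.4 °C, SSS 34.2 psu, current 3.29 cm/s, flat over CHL-a 0.18–1.5
mg/m³, salinity-dominant) — so every stage is testable with known ground
truth.

## Worked example

```r
library(bandapfz)

cfg    <- generator_config(seed = 42)
fields <- generate_env_fields(cfg)
records <- generate_catch_records(fields, cfg)

# fishing season -------------------------------------------------------
si <- fishing_season_index(aggregate_monthly(records))
subset(season_report(si), season != "Regular season")
#>        month    cpue     fsi std_dev         season
#> 1    January 215.358 157.499  11.273 Fishing season
#> 3      March  35.853  26.044   1.734    Lean season
#> 4      April  12.462   9.122   0.876    Lean season
#> 5        May   7.765   5.690   0.286    Lean season
#> 6       June  12.062   9.088   0.748    Lean season
#> 7       July  35.144  25.680   1.107    Lean season
#> 9  September 224.242 163.119   8.559 Fishing season
#> 10   October 290.727 212.821  12.981 Fishing season
#> 11  November 307.711 222.502   7.699    Peak season
#> 12  December 289.469 210.855  12.803 Fishing season
sum(si$fsi)
#> [1] 1200
```

November is the peak season — the monsoon-transition month where the
generator's seasonal cycles align with the response optima — and the
twelve indices sum to 1200 by construction, so each FSI reads as a
percentage of an average month: November's 222.5 means more than double
the average catch rate, while the March–July lean stretch runs at a
tenth of it or less.

```r
# habitat model --------------------------------------------------------
tab <- build_training_table(records, fields)
fit <- train_ann(tab, config = train_config(seed = 42, max_epochs = 6000,
                                            patience = 6000))
fit$test
#> test evaluation (n = 1282): MSE 3637.2116, RMSE 60.3093, MAPE 31.24%

test_rows <- split_train_test(tab, train_config(seed = 42))$test
permutation_importance(fit$model, test_rows, seed = 1)
#>   predictor raw_importance    percent
#> 1       sst      255.95007  2.0510606
#> 2       chl       16.46349  0.1319305
#> 3       sss     8816.06977 70.6477379
#> 4   current     3390.42970 27.1692710

# potential fishing zone for the last November -------------------------
g <- predict_grid(fit$model, fields, 59)   # month index 59 = Nov 2023
locate_maximum(g, fields)
#> Hotspot, month 59: 360.1 kg/trip at 125.375E, -4.875 lat
#>   SST 31.09 degC, CHL-a 0.978 mg/m3, SSS 33.89 psu, current 3.87 cm/s
export_map(g, "pfz_nov2023.csv")
```

The held-out error here is dominated by the generator's default 35%
multiplicative catch noise (a trip-level CV typical of purse-seine
landings); the model's fit to the underlying response is much tighter —
at 5% observation noise the held-out range-normalized RMSE drops to
about 2.5% (recomputed by `scripts/acceptance.R` below).

Salinity dominates the contribution ranking with current second, as
built into the generator, and the predicted hotspot sits on conditions
close to the configured optima.  The `run_simulate()`, `run_fsi()` and
`run_train_map()` functions chain these stages from a single YAML
configuration with one global seed.

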