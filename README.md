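# aascall

Spatiotemporal analysis of fish aggregation-associated sound (AAS)
detections across a hydrophone array.

Passive acoustic monitoring of fish spawning aggregations (FSAs) — dense,
transient gatherings of fish such as Nassau Grouper — records the calls the
fish produce at the site. A single hydrophone cannot separate *when the fish
call* from *where the fish are*; an array of hydrophones spaced along the
site can. `aascall` is for bioacousticians and quantitative ecologists
working with such arrays. It provides, as tested tabular (tibble-in,
tibble-out) building blocks:

* **a seeded synthetic-data generator** — great-circle array geometry,
  a fish-mass trajectory with 20 m / 100 m proximity categories, hourly
  counts from the hierarchical Poisson process below, per-minute detection
  streams in 2-s bins with vessel-interference minutes, and paired
  true/predicted classifier streams;
* **detection preprocessing** — 2-s dedup binning (earliest call per bin),
  1-in-5 annotation subsampling, ±2-minute interference exclusion windows,
  per-hour effort computation, hourly aggregation, MaxN abundance and
  composite proximity categorisation;
* **classifier evaluation** — confusion matrices between true and predicted
  streams (bin-level presences, whole empty minutes as true negatives),
  accuracy/rate metrics and Cohen's kappa, pooling across stations with
  printed-total bookkeeping;
* **the call-rate model** — a Bayesian hierarchical Poisson regression with
  an effort offset, fit by a built-in Hamiltonian Monte Carlo sampler:

  ```
  V[j,i] ~ Poisson(mu[j,i])
  log mu[j,i] = log tau[j,i] + T[i] + D[i] + FP[j,i] + h[j,i]
  h[.,i]      ~ MVN(0, diag(sigma_h) R diag(sigma_h))
  T, D, FP    ~ Normal(0, 1);  sigma_h ~ Exponential(1);  R ~ LKJ(1)
  ```

  with 24 hour-of-day effects `T`, 7 day-after-first-spawn effects `D`
  (−4..+2), 3 fish-proximity effects `FP`, and hour-level station random
  effects `h` whose correlation matrix `R` is the spatial quantity of
  interest;
* **spatial analysis** — haversine station distances, posterior pair
  correlation summaries, and the correlation-versus-distance regression
  with its zero crossing.

## Worked example

```r
library(aascall)
library(dplyr)

# 1. synthesise a 3-station, 72-hour deployment
cfg <- sim_config(n_stations = 3, n_hours = 72, seed = 42)
sim <- simulate_dataset(cfg)

# 2. preprocess: annotate, exclude interference windows, aggregate hourly
mm <- sim$minutes %>% subsample_minutes() %>% expand_interference()
hc <- aggregate_hourly(filter_events_observed(sim$events, mm), mm,
                       covariates = sim$hourcells)
head(hc, 3)
#>   station_id          hour_start minutes_observed       tau V rate T_index D_index FP_index
#> 1        LS1 2020-02-08 10:00:00               60 1.0000000 1    1      10       0        0
#> 2        LS1 2020-02-08 11:00:00               60 1.0000000 1    1      11       0        0
#> 3        LS1 2020-02-08 12:00:00               58 0.9666667 0    0      12       0        0
```

`tau` is the exposure: hour 12:00 lost two minutes to an interference
window, so its count is normalised by 58/60 of an hour.

```r
# 3. fit the call-rate model (3 chains x 1000 iterations, ~2 min here)
fit <- fit_call_model(encode_design(hc), chains = 3, iterations = 1000,
                      seed = 1)
glance(fit)
#>   chains iterations warmup draws max_rhat  min_ess converged mean_accept   mean_lp
#> 1      3       1000    500  1500 1.021797 71.77783      TRUE   0.8987566 -557.3033

predict_effects(fit) %>% filter(factor == "FP")
#>   factor level   median       q25      q75 whisker_lo whisker_hi
#> 1     FP     0 1.181452 0.9010467 1.565895  0.3393444   2.548499
#> 2     FP     1 1.792848 1.3662424 2.357735  0.4579318   3.836331
#> 3     FP     2 3.702208 2.7083485 4.860485  0.9510899   8.075526
```

All split R-hat are below 1.05 and the proximity effects rise with
category: hours with the fish mass within 20 m of a station
(`level 2`) have roughly three times the call rate of hours with no fish
within 100 m, on the multiplicative (rate) scale.

```r
# 4. spatial decay of the station correlations
pairs <- correlation_pairs(fit, sim$geometry)
pairs
#>   station_a station_b distance_m  rho_median    rho_q25   rho_q75
#> 1       LS3       ST2        150  0.58947003  0.4366539 0.7145778
#> 2       LS1       ST2        150  0.48375550  0.2924538 0.6307276
#> 3       LS1       LS3        300 -0.01263092 -0.2197969 0.1869599

corr_distance_regression(pairs)
#> <aas_corr_reg>
#>   rho = 1.0859 -0.00366 * distance_m (zero crossing 297 m)
```

Adjacent stations (150 m) track each other strongly; 300 m apart the hourly
series are essentially uncorrelated, and the fitted line crosses zero at
about 300 m for this short synthetic deployment. `autoplot()` on the fit
and on the regression object draws the effect box plots and the
correlation–distance scatter with its confidence band.

A benchmark table of published confusion counts for an automatic
grouper-call classifier (FADAR) evaluated against manual annotation ships
with the package:

```r
bench <- fadar_benchmark()
confusion_metrics(pool_confusion(bench[bench$classifier == "FADAR", ]))
#>   kappa accuracy  mcr   tpr  tnr  fpr   fnr
#> 1 0.516     0.76 0.24 0.532 0.98 0.02 0.468
```

`run_pipeline(cfg, out_dir)` orchestrates all stages (simulate →
preprocess → evaluate → fit → spatial → report) with CSV outputs and a
checksummed JSON run manifest; `inst/scripts/run-pipeline.R` is a thin
command-line wrapper over it.

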