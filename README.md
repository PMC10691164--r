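# migcues

Movement ecologists increasingly ask whether the migratory decisions of
individual animals track the *fine-scale* environment those individuals
actually experience — not just the regional climate. `migcues` implements a
complete analysis chain for that question in partially migratory birds
tracked by GPS: some individuals of a population migrate tens to hundreds of
kilometres after breeding while others stay resident, and the timing of
departure may respond to local food availability (vegetation greenness),
heat exposure, and the availability of cool *microclimate refugia* —
spots whose minimum temperature within 500 m is at least 0.5 °C below the
local median, where a heat-sensitive grassland bird can shelter.

The package covers, as composable tibble-in/tibble-out functions:

* **Trajectory phenology** — daily centroids from raw fixes; a breeding
  reference centroid; departure detection (first date the bird stays > 1.5 km
  from the reference for at least one month); return detection; residency
  classification; censoring; and migration distance (both the cumulative
  daily-distance sum and the breeding-to-post-breeding site distance).
* **Microclimate sampling** — per-fix temperature at the nearest hour, the
  minimum and median over all grid cells within a 500 m geodesic buffer, the
  refugium indicator `median − min ≥ 0.5 °C`, and NDVI
  (`(NIR − Red)/(NIR + Red)`) from the nearest 8-day composite.
* **Relative exposure indices** — a population-level penalized cubic
  regression spline (basis dimension 10, GCV smoothing) of day-averaged
  temperature or NDVI against Julian date; each bird's index is the **sum of
  its residuals** from that curve over its seasonal window (1 May → departure
  for breeding; arrival → 15 September for post-breeding). Positive = hotter
  (or greener) than the population norm for those dates.
* **Repeatability** — the intra-class correlation
  R = σ²_individual / (σ²_individual + σ²_residual) of departure date, return
  date and migration distance from a Gaussian mixed model with individual and
  population random intercepts, with a 1000-iteration parametric-bootstrap
  percentile interval. R is "significant" when the interval excludes 0.
* **Cue models** — mixed-effects models of departure day (Gaussian, bird
  random intercept) and of the probability of a late return (binomial logit,
  returns dichotomised at 30 November), AICc-ranked over all admissible
  candidate term sets with the ΔAICc < 2 plausible set flagged, |r| ≥ 0.7 /
  VIF ≥ 3 collinearity screening, and spline-correlogram diagnostics of
  residual spatial autocorrelation (500 bootstrap resamples).
* **A synthetic world** — seeded landscapes (hourly temperature fields with
  cool patches, senescing NDVI composites) and multi-year GPS tracks whose
  true departure dates are a known linear function of the birds'
  environmental covariates, so every stage can be validated against ground
  truth.

## Worked example

```r
library(migcues)

land <- simulate_landscape(landscape_config(seed = 42))
sim  <- simulate_tracks(land, n_birds = 20, years = 2, n_residents = 2,
                        seed = 42)
run  <- run_pipeline(sim$fixes, land,
                     run_config(n_boot_repeatability = 500, seed = 42))
run
#> <migcues_run> 20 birds, 40 bird-seasons (36 migrant / 4 resident), 20 excluded
#> # A tibble: 3 × 7
#>   trait         R ci_low ci_high significant n_individuals n_observations
#>   <chr>     <dbl>  <dbl>   <dbl> <lgl>               <int>          <int>
#> 1 distance  1.000  1.000   1.000 TRUE                   18             36
#> 2 departure 0.911  0.787   0.962 TRUE                   18             36
#> 3 return    0.116  0       0.493 FALSE                  18             36
```

The run report reads: 20 excluded bird-seasons are the 1 April – 30 April
carry-over stubs of the final tracking spring (too short to classify).
Migration distance is perfectly repeatable here because simulated birds reuse
the same post-breeding site every year; departure timing is strongly
repeatable because bird-constant covariate effects and the individual
intercept both contribute between-individual variance; return timing is
noisy, so its interval reaches 0 (not significant). The median detected
departure in this cohort is day-of-year 169 (mid June).

Collinearity screening and the AICc table for the departure model:

```r
tidy(run$collinearity)
#> # A tibble: 3 × 3
#>   covariate     vif max_abs_r
#>   <chr>       <dbl>     <dbl>
#> 1 refugia_pct  1.03     0.133
#> 2 rel_temp     1.04     0.155
#> 3 rel_ndvi     1.05     0.155

tibble::as_tibble(run$departure_selection)[1:4, c(1, 2, 4, 5, 6, 7)]
#> # A tibble: 4 × 6
#>   model           k  AICc delta_AICc weight in_plausible_set
#>   <chr>       <int> <dbl>      <dbl>  <dbl> <lgl>
#> 1 (null)          3  241.       0     0.358 TRUE
#> 2 refugia_pct     4  242.       1.13  0.204 TRUE
#> 3 rel_ndvi        4  243.       1.88  0.140 TRUE
#> 4 rel_temp        4  244.       2.54  0.101 FALSE
```

With only 18 analysable birds the environmental signal is weak relative to
the individual intercepts, and the null model tops the table — covariate
effects on timing are better demonstrated with the direct frame simulator,
which generates the model frame at configurable effect sizes:

```r
f <- simulate_model_frame(n_birds = 30, years = 2,
                          beta = c(rel_ndvi = 8), resid_sd = 3, seed = 16)
tidy(fit_departure_model(f, "rel_ndvi"))
#> # A tibble: 2 × 6
#>   term        estimate std_error    df statistic  p_value
#>   <chr>          <dbl>     <dbl> <dbl>     <dbl>    <dbl>
#> 1 (Intercept)   171.       0.540  28.9     317.  9.88e-53
#> 2 rel_ndvi        7.70     0.539  55.8      14.3 2.84e-20
```

A true effect of +8 days of delayed departure per standard deviation of
relative NDVI is estimated at 7.7 ± 0.5 days.

Plots: `autoplot()` methods exist for repeatability sets (forest plot),
selection tables, population smooths and spline correlograms, plus
`plot_departure_dates()` for the phenology distribution.

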