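---
title: "Models and methods in migcues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in migcues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`migcues` links the migratory phenology of a partially migratory,
heat-sensitive grassland bird to the fine-scale environment each individual
experiences. This vignette documents the models, the conventions behind every
threshold, the numerical choices, and what the synthetic world does and does
not emulate. It states no empirical result beyond what the package's own
tests and `scripts/acceptance.R` compute.

## 1. Phenology from trajectories

**Daily centroids.** Each bird-day is summarised by the arithmetic mean of
its fix coordinates over the UTC day. Duplicate (bird, timestamp) rows are
dropped with a warning; unparseable timestamps abort with the row index.

**Season-years.** A breeding season-year runs 1 April – 31 March, so
midwinter returns stay attached to the breeding season they follow.

**Breeding reference.** Departure and return are measured against a single
reference point per bird-season. Its definition is circular — the reference
is the mean centroid of the breeding season, but the breeding season ends at
the departure that the reference is used to detect. We resolve this in two
passes. Pass 1 takes the **componentwise median** of the first
`min_predeparture_days` (7) observed days. Birds are captured at the breeding
area, and every retained bird-season has at least seven pre-departure days by
the eligibility rule, so this capture window is pre-departure by
construction; the median tolerates a minority of early away-days. Pass 2
recomputes the reference as the **mean** centroid over capture → departure
and re-detects, iterating (at most three times) until the detected departure
is stable; on clean tracks one step suffices. A plain mean over a
capture-to-31-May provisional window fails whenever most of that window is
post-departure (e.g. capture 26 April, departure 1 May), which is why the
capture-window median is used instead.

**Departure rule.** Departure is the first date from which the daily
centroid stays more than `radius_km` from the reference for at least
`min_away_days`. Defaults: 1.5 km — the same threshold that defines
residency, used for both directions so "in" and "out" are one coherent
partition — and 30 days (one month). Birds with no qualifying run are
residents; a run still open when the track ends is **censored** (no date is
emitted, the bird-season is excluded with reason
`track_ended_before_one_month`).

**Observation gaps.** Tags duty-cycle and fail; unobserved gaps of up to
`max_gap_days` (3) calendar days inside a run inherit the run's state, longer
gaps break it. This is a package convention — tracking literature offers no
single rule — and it is symmetric between away-runs and home-runs.

**Residency coverage.** A bird-season may only be classified resident if it
is observed through 1 September; a spring-only track fragment is excluded
(`insufficient_season_coverage`) because residency cannot be distinguished
from an unobserved later departure.

**Return.** The first date after departure with the centroid back within
`radius_km`, sustained `min_back_days` (7); otherwise censored
(`track_ended`).

**Distance.** Two scalars per migrant: `distance_cumulative_km`, the sum over
observed post-breeding days of the geodesic distance between the reference
and that day's centroid; and `distance_site_km`, the distance from the
reference to the mean post-breeding centroid. The cumulative sum grows with
tracking duration, so it is unsuitable as a per-bird-year scalar for
between-year repeatability; `distance_site_km` is the default trait, with the
cumulative variant retained (`distance_cumulative`) for completeness.

All metric geometry uses ellipsoidal (WGS84) distances via `geosphere`;
planar approximations distort 400 km movements at these latitudes.

## 2. Microclimate and NDVI extraction

Per fix: the temperature of the containing grid cell at the **nearest hour**
(ties to the earlier hour); the minimum and median over all cells whose
centre lies within 500 m **geodesic** distance of the fix (membership by
cell-centre distance, not area intersection — the usual raster-extraction
semantics, and the convention that keeps the exhaustive-enumeration oracle
exact); and the refugium indicator, true when `median − min ≥ 0.5 °C`
(inclusive, per "at least 0.5 °C cooler"). Medians with an even cell count
use the conventional midpoint rule. A buffer truncated by the grid edge flags
the sample `buffer_complete = FALSE`; such fixes are excluded from the
refugia-percentage denominator.

The refugium indicator is computed **per fix on hourly values** and
aggregated over fixes (`refugia_pct` = percentage of a bird-season's valid
GPS fixes with an available refugium). Day-averaging applies to the
temperature covariates, not to the indicator; whether the original analysis
flagged refugia on hourly or day-averaged buffers is ambiguous, so
`summarize_season(basis = "daily")` provides the alternative.

NDVI is `(NIR − Red)/(NIR + Red)`; fixes take the value of the 8-day
composite nearest in date, ties to the earlier composite.

Windows: breeding = 1 May → departure; post-breeding = arrival (under the
one-day relocation model, the departure day) → 15 September.

## 3. Relative exposure indices

A single population-level smooth per phase and response: a Gaussian penalized
cubic regression spline of the pooled day-averaged values against Julian date
(day-of-year, 1 January = 1), basis dimension 10, smoothing parameter by GCV
(`mgcv::gam`). Each bird's index is the **sum** (not mean — window length is
part of the signal) of its daily residuals from that curve over its window;
missing days are simply absent, never imputed. Identities that follow from
the construction and are enforced by tests: a bird lying on the curve scores
~0; adding c to every daily value adds exactly c·n_days; the index is
additive over disjoint windows. One reading of the original description fits
a per-individual NDVI smooth; we implement the population-level smooth for
both responses, consistent with the temperature index and with residuals
"relative to the studied population".

Smooths serialize to JSON as their fitted values on the integer-day training
grid plus the smoothing parameter. Every consumer evaluates the smooth at
integer days only, so this representation gives exact reuse without
reconstructing a spline basis from raw knots.

## 4. Repeatability

R = σ²_individual / (σ²_individual + σ²_residual) from a REML Gaussian mixed
model with random intercepts for individual and for breeding population. The
population variance is partialled out and **excluded from the denominator**
(adjusted repeatability — the standard convention when a grouping factor is
fitted to control for it); `population_in_denominator = TRUE` gives the
unadjusted alternative. Dates enter as day-of-year (departure) or days since
1 September (return — continuous across 31 December). Residents contribute to
the distance trait (their site distance is defined) and are excluded from
timing traits, where they have no value.

Uncertainty: parametric bootstrap, default 1000 iterations — each simulates a
response vector from the fitted model, refits, recomputes R; the 2.5/97.5
percentiles form the interval. Replicate seeds derive from the master seed by
a counter; non-converging replicates are dropped and counted, with an error
if more than 5% drop. An estimate is "significant" when the interval excludes
zero. Boundary fits (individual variance → 0) report R = 0 with a flag.

## 5. Cue models and selection

Departure: Gaussian mixed model of departure day-of-year with a bird random
intercept, REML for the reported fit (`lmerTest`, Satterthwaite df on the
coefficient tests) but **maximum likelihood for AICc comparison** — REML
likelihoods are not comparable across fixed-effect structures. Candidates:
all subsets of {refugia_pct, rel_temp, rel_ndvi, refugia_pct:rel_temp} with
the marginality constraint (the interaction only enters with both mains) —
ten models including the null. `marginal_refugia_slope()` reads the fitted
refugia effect as a function of temperature exposure, the readout for
"the refugia benefit shrinks under hot conditions".

Return: binomial logit mixed model of a late return (after 30 November —
returns are strongly bimodal, so they are dichotomised rather than modelled
as dates), candidates limited to three terms from the six breeding +
post-breeding covariates. Complete separation is plausible at these sample
sizes; the fallback refits on the data augmented with every row mirrored at
flipped response and prior weight 0.05 — a shrinkage penalty toward even odds
— flagged `penalized`, using `nAGQ = 0` (the Laplace step is unreliable under
fractional prior weights). Penalized likelihoods are not comparable with
plain ones, so AICc always uses the unpenalized fit when one exists.

AICc = AIC + 2k(k+1)/(n−k−1) with k the log-likelihood df (fixed effects +
variance parameters); candidates with n−k−1 ≤ 0 are skipped with a warning;
ties rank the smaller model first; Akaike weights are normalized over the
fitted set; the plausible set is ΔAICc < 2.

Collinearity: pairwise |r| ≥ 0.7 and VIF ≥ 3 are reported as violations,
never auto-dropped; a perfectly collinear covariate reports an infinite VIF.

Spline correlogram: residuals are standardized; products of all location
pairs are smoothed against pairwise geodesic distance with a smoothing spline
(df 6); the 95% pointwise envelope resamples locations with replacement
(default 500 times), excluding same-location self-pairs. It is a diagnostic
only — no spatially explicit model is fitted.

## 6. The synthetic world

The simulator defines the study conditions under which everything is tested.

*Landscape.* A 100 × 100 grid of 30 m cells (3 km × 3 km). Temperature =
diel cosine (min 18 °C near 02:00, max 36 °C near 14:00 at season start) +
0.05 °C/day seasonal warming — peaking near 44 °C in September, matching a
hot Iberian summer — + a static per-cell anomaly: −1.0 °C on twelve 3 × 3
refugia patches plus N(0, 0.1 °C) cell noise. The noise SD matters: the
minimum over the ~870 cells of a 500 m buffer of N(0, σ) noise alone is about
−3.2σ, so σ must stay below ~0.15 °C for the 0.5 °C indicator to reflect true
patches rather than noise extremes. NDVI = a smoothed spatial greenness field
(0.2–0.9) times a seasonal factor: plateau until day 120 (late April), then
linear senescence at 0.006/day — green springs drying through June. The
seasonal curves are annually periodic so multi-year tracks see the same
season each year, and the landscape is **spatially periodic**: sampling
canonicalizes any point into the grid modulo its extent, so a post-breeding
site 400 km away experiences a statistically identical world
(`wrap = FALSE` restores an error for out-of-extent points).

*Birds.* Breeding sites are interior cell centres; post-breeding sites are
drawn log-uniformly at 4–421 km (the observed span of this study system) in a
random direction, re-drawn if their canonical position falls too close to a
grid edge. Migration is a one-day relocation (departure is a date, not a
path; no stopovers). True departure day = 171 (20 June, the observed median)
+ effects-per-SD of the bird's deterministic site covariates (greenness,
temperature anomaly, refugia fraction within 500 m; defaults +8 NDVI, +4
refugia, 0 temperature, −3 refugia × temperature days/SD, matching the
direction and rough size of the reported effects) + an individual intercept
(SD 4 days, shared across years) + yearly noise (SD 3 days — the residual
scale the mixed-model class expects). True returns are 89 days after
1 September (29 November, the observed median) ± 30 days with a 10-day
individual intercept, clamped to late September – mid March. Fixes scatter
around the active site with 150 m home-range SD plus 25 m GPS error (GPS
error magnitude is unreported for the real tags; 25 m is a typical modern GPS
figure, and a free parameter). Fix interval defaults to 120 min, the 2 h
duty cycle.

*What it does not emulate:* behavioural realism (lekking bouts, flight
paths, wind), stopovers, multiple post-breeding sites, device duty-cycle
failure patterns beyond an optional uniform dropout, MODIS quality screening,
and — importantly — year-to-year variation in site use: simulated birds reuse
sites exactly, so simulated distance repeatability is ~1 rather than the
moderate values real birds show. Passing tests therefore demonstrate that the
estimators recover truth under the stated generative model, not that real
data meet that model.

## 7. Numerical and design choices

* Geometry: WGS84 throughout, `geosphere::distGeo`; grid cell centres are
  spaced metrically from the origin.
* Nearest-hour and nearest-composite matching both break ties toward the
  earlier instant.
* Medians: midpoint rule for even counts (componentwise for the pass-1
  reference).
* Seeds: every stochastic routine takes an explicit seed; internal replicate
  seeds derive from it by a fixed integer recurrence kept below 2³¹.
* Degenerate inputs: constant smooth responses warn and fit flat; empty
  windows yield NA indices with a message; all-identical correlogram
  locations error; `min > median` buffer statistics error (upstream bug by
  construction).
* The pipeline (`run_pipeline()`) never mutates inputs, writes each stage as
  CSV (plus a YAML manifest with config hash, version and exclusion counts)
  for stage-level resume, and skips — with a manifest note — statistical
  stages whose sample-size preconditions fail (e.g. repeatability with
  single-season tracking).
* Problem sizes in the verification suite: 25 random grids × 50 fixes for
  the buffer oracle; 110-bird cohorts for phenology recovery; 20 replicate
  40 × 3 panels (bootstrap 200, plus one at 1000) for ICC recovery; 50
  replicate 60-row frames for effect recovery and for null behaviour.

## 8. Known limitations

* The refugium threshold interacts with grid noise (see §6); with real
  microclimate surfaces the 0.5 °C criterion should be checked against sensor
  accuracy.
* The return model dichotomises dates; information near the 30 November
  cutoff is discarded by design.
* Departure-date candidate models assume Gaussian errors on day-of-year;
  heavily skewed departure distributions would need a different family.
* `distance_cumulative_km` depends on tracking effort and should not be
  compared across unequal tracking durations.
* The spatial-periodicity device means simulated "distant" environments are
  replicas, not genuinely different climates; carry-over effects of truly
  distinct post-breeding regions cannot be studied with it.
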