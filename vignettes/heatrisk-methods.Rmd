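---
title: "Methods: conditional Heat Index estimation and scenario projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conditional Heat Index estimation and scenario projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(heatrisk)
```

## The problem

Heat-health early warning in humid cities needs an exposure metric that
reflects physiology, not just air temperature. The Heat Index (HI) is the
apparent temperature adopted by the U.S. National Weather Service: a
regression surface over dry-bulb temperature and relative humidity that
approximates Steadman's biophysical apparent-temperature tables. `heatrisk`
implements the HI computation, classifies records into operational risk
bands, models the conditional dynamics of HI at 3-hourly resolution, and
projects HI forward under climatological scenarios with empirical
uncertainty bands.

Because HI is a deterministic transform of temperature and humidity,
everything downstream is *conditional estimation*, not independent
forecasting: models learn the temporal persistence and nonlinear structure
of HI given meteorological inputs, and multi-year outputs are
scenario explorations under stated assumptions, not weather forecasts.

## The two-stage HI computation

Stage 1 evaluates the simplified Steadman form
`0.5 [T + 61 + 1.2 (T − 68) + 0.094 RH]` (T in °F). Two conventions
coexist in published renderings of the procedure, so a `mode` switch
exposes both: `"average"` (default)
averages the simple value with T; `"nws"` uses the simple value directly
(canonically that value *is* already the average). Below 80 °F the
preliminary value is the final HI. At or above 80 °F the nine-term
Rothfusz regression replaces it, minus a low-humidity adjustment
(RH < 13 %, 80–112 °F), plus a high-humidity adjustment (RH > 85 %,
80–87 °F). The Stage-1 coefficient is 1.2 — sources occasionally typeset
it as 12, which would be dimensionally absurd — and the low-humidity
adjustment is the canonical `((13 − RH)/4)·√((17 − |T − 95|)/17)`; a unit
test pins both. All arithmetic is double precision; nothing is rounded
before categorisation. Category bins are lower-inclusive/upper-exclusive
(27/32/41/54 °C), so the printed overlapping bin edges resolve
deterministically.

## The synthetic generator

`generate_climate()` emulates a decade of Dhaka-like station data on the
3-hourly synoptic grid: temperature = mean + annual sinusoid + diurnal
sinusoid + AR(1) noise (initialised at its stationary distribution, so
there is no burn-in transient), humidity = baseline + coupling × (T −
mean) + white noise, clipped to [5, 100] % — the lower clip keeps the
low-humidity HI branch reachable while excluding physically absurd 0 %.

Defaults were chosen once to reproduce the published descriptive moments
of the Dhaka record the generator stands in for: mean 25.1 °C, annual
amplitude 5.7 °C peaking mid-June, diurnal amplitude 3 °C peaking 12:00,
AR(1) coefficient 0.8 with innovation SD 1.2 °C at the 3-hour step,
humidity baseline 75 % with coupling −0.6 %/°C and noise SD 8 pp. Under
the closed-form variance decomposition these imply corr(T, RH) ≈ −0.35 and
Jun–Aug/Dec–Feb mean temperatures of 29.5/20.7 °C. The annual peak is
placed in June rather than May because, with a pure sinusoid, matching
both seasonal means from a May peak would require a ~10 °C amplitude;
mid-June reproduces them with a realistic 5.7 °C. Both peak positions are
configurable.

What the generator does *not* emulate: monsoon asymmetry of the annual
cycle, the real (positive) summer-humidity regime of South Asia, multi-day
synoptic persistence beyond AR(1), and trends. Tests passing on synthetic
data therefore demonstrate pipeline correctness and qualitative behaviour,
not climatological fidelity of any particular number.

## QC and preprocessing

Wide tables (rows keyed Year/Month/Day, one column per synoptic hour) are
reshaped to long, strictly date-validated (February 30 is an error, not an
NA), and inner-joined on the (year, month, day, hour) key; duplicate keys
abort. Continuity is checked against the complete 3-hour grid; by default
any gap is a hard failure, preserving the complete-grid assumption that
the lag features rely on. Outliers are flagged by the 1.5 × IQR rule with
type-7 (linear-interpolation) quantiles — flagged, never removed, since
extremes in station data are usually genuine weather. Min-max scaling is
fitted on the training partition only and applied to the machine-learning
inputs; statistical adapters receive raw values. VIF uses the standard
1/(1 − R²) auxiliary-regression definition and reports `Inf` for exact
collinearity.

## Models and evaluation

`build_features()` produces, per timestamp: raw T and RH, hour,
day-of-month, month, one-hot season (meteorological quarters, winter =
Dec–Feb), and HI lags at 1, 3, 6 steps taken strictly from the past; rows
without full lag history are dropped. The registry:

* `naive` — persistence, the MASE benchmark.
* `arimax` — `stats::arima` with order (2,0,2) and exogenous T, RH and
  season dummies (winter baseline; calendar integers excluded to avoid
  spurious linear trends). CSS estimation for speed and robustness at
  n ≈ 23,000.
* `sarimax` — (1,0,1)(1,0,1) with period 8, the daily cycle on the
  3-hourly grid.
* `rfr` — random forest, 300 trees, square-root feature subsampling,
  unrestricted depth; lags included.
* `gboost` — gradient boosting, 500 rounds, learning rate 0.05, depth 6,
  early stopping on the chronological tail 10 % of the training rows
  (never a random split, which would leak future data into training).

There is no canonical hyperparameter set for this task; these defaults
are the package's own documented choices and all are overridable via
`params`. Lags feed the ML adapters only, while the linear adapters model
persistence through their ARMA structure — mixing lagged targets into the
exogenous block of an ARMA model would double-count its autoregression.

Test-set predictions for the linear adapters are one-step-ahead: the
model is re-filtered over train + test with coefficients *fixed* at their
training estimates, so parameters never see the test period (verified by
mutation tests). Expanding-window CV cuts the training rows into
`folds + 1` equal blocks — block 1 is the initial training window, the
rest are validation blocks — because validation fifths with an empty
first training set would be degenerate. Grid search minimises mean CV
RMSE with first-in-grid tie-breaking and never touches the test
partition.

Metrics follow the standard definitions; MASE uses the in-sample mean
absolute error of the m = 1 (3-hour) persistence benchmark as
denominator, errors on constant series (zero denominator), and MAPE is
reported absent with a warning when any observation is zero.
Durbin–Watson is `Σ(Δe)²/Σe²`; Breusch–Pagan uses the studentised
(Koenker) `n·R²` form with fitted values as the default auxiliary
regressor, the conventional choice when the original regressor set is
unspecified.

## Scenario projection

Monthly climatology (per-calendar-month means over the historical record)
is expanded as constants within each month — deliberately without a
synthetic diurnal cycle, following the projection design literally; an
analyst wanting diurnal structure can supply a custom future series.
Scenario presets shift the climatology by (−0.5 °C, −2 pp), (0, 0),
(+1.0 °C, +3 pp) with Gaussian noise SDs of 0.5/1.0/1.5 °C and 2/4/6 pp
for the low/moderate/elevated levels (chosen as ordered magnitudes spanning typical intra-month dispersion,
and configurable). Scenario weather is drawn once per scenario seed, so a
scenario is a fixed future, not a re-randomised ensemble.

The recursive engine steps 3 h at a time: lag features are read from the
concatenation of the six initialising observed HI values and all previous
predictions. For the forest, every step retains all 300 per-tree
predictions; the point is their mean and the 95 % band their empirical
2.5/97.5 percentiles (type-7 interpolation, so bounds are
bit-reproducible). Tree-level dispersion reflects model uncertainty under
fixed inputs, not future weather variance — coverage on held-out data is
typically conservative. Non-forest models yield point trajectories only.
Because `predict.randomForest` re-marshals the forest on every call, the
per-step evaluation uses an internal packed-tree traversal that is
exactly equivalent (tested against `predict.all`) and ~40× faster.

## Problem sizes and numerical choices

The shipped tests exercise the full decade-scale study (29,216 records,
forest trained on 2014–2021, three 4-year recursive projections of 11,688
steps each) once, and use 1–3-year series elsewhere; these sizes were
chosen to keep a complete run comfortably reproducible on a laptop while
still covering every code path at scale. Ties in quantiles, category
boundaries (lower-inclusive), and the 80 °F branch point (tested on the
preliminary value, ≥) are all fixed conventions documented above.
Seeds: a single master seed drives every stochastic component;
per-component seeds are derived deterministically from it.

## Known limitations

* Scenario projections inherit the climatological stationarity
  assumption: no warming trend beyond the scenario's constant shift, no
  diurnal cycle in future predictors, noise independent across steps.
* Empirical tree intervals under-represent aleatoric uncertainty at
  horizons where recursive error accumulates.
* The linear adapters use fixed, documented orders; no automatic order
  selection.
* A recurrent neural estimator is intentionally out of scope; the
  registry is extensible through the same adapter surface.
* Only CSV is written for fixtures (XLSX is read if `readxl` is
  available).
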