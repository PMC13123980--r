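# heatrisk

Conditional estimation and scenario-based projection of the Heat Index (HI)
for heat-health early warning, at 3-hourly (synoptic) resolution.

Temperature-only heat warnings underestimate physiological stress in humid
climates: at the same air temperature, high humidity blocks evaporative
cooling. The HI is the standard apparent-temperature metric that folds
relative humidity into a single physiologically meaningful number, and
public-health agencies attach intervention thresholds directly to it.
`heatrisk` is aimed at analysts building such early-warning pipelines from
station records of dry-bulb temperature (°C) and relative humidity (%) on
the 3-hourly synoptic grid (00, 03, ..., 21).

## What it computes

**Heat Index (two-stage NWS procedure).** With T in °F and RH in %:

1. *Stage 1 (Steadman):* `HI_simple = 0.5 [T + 61.0 + 1.2 (T − 68.0) + 0.094 RH]`,
   averaged with T to give the preliminary HI.
2. *Stage 2 (Rothfusz):* when the preliminary HI ≥ 80 °F, the nine-term
   regression
   `HI = −42.379 + 2.04901523 T + 10.14333127 RH − 0.22475541 T·RH − 0.00683783 T² − 0.05481717 RH² + 0.00122874 T²RH + 0.00085282 T·RH² − 0.00000199 T²RH²`
   with a low-humidity adjustment `((13 − RH)/4)·√((17 − |T − 95|)/17)`
   subtracted for RH < 13 %, 80–112 °F, and a high-humidity adjustment
   `((RH − 85)/10)·((87 − T)/5)` added for RH > 85 %, 80–87 °F.

Results are reported in °C and classified into NWS risk categories:
Normal (< 27 °C), Caution [27, 32), Extreme Caution [32, 41),
Danger [41, 54), Extreme Danger (≥ 54).

**Conditional estimation.** Because HI is a deterministic function of T and
RH, the modelling task is conditional: estimate HI dynamics from
meteorological predictors, calendar features and leakage-safe lagged HI
(1, 3, 6 steps, strictly past). `heatfit()` fits one of a registry —
persistence baseline, ARIMAX, SARIMAX (period 8 = daily cycle), random
forest, gradient boosting — on a chronological split, with expanding-window
cross-validation, Durbin–Watson / Breusch–Pagan residual diagnostics, and
MSE/RMSE/MAE/MAPE/MASE/R² metrics (MASE scales by the 3-hour persistence
benchmark; < 1 means the model beats no-change forecasting).

**Scenario projection.** Future predictors come from monthly climatology
with scenario shifts — optimistic (−0.5 °C, −2 pp), moderate (0, 0),
pessimistic (+1.0 °C, +3 pp) — plus seeded Gaussian variability. HI is
projected recursively 3 h ahead over multi-year horizons, lag features fed
by previous predictions, with empirical 95 % prediction intervals from the
2.5th/97.5th percentiles of per-tree forest predictions.

A seeded synthetic generator (`generate_climate()`) produces Dhaka-like
gap-free series (annual + diurnal cycles, AR(1) noise, negatively coupled
humidity) so the full pipeline is testable end to end without any data
download.

## Worked example

```r
library(heatrisk)

series <- generate_climate(synthetic_config("2019-01-01", "2021-12-31"))
hs  <- heat_index(series)
fm  <- build_features(hs)
sp  <- chronological_split(fm, "2021-01-01")

fit <- heatfit(sp$train, model = "rfr", seed = 42)
print(compute_metrics(sp$test$hi, predict(fit, sp$test)))
#> n=2920  MSE 1.1747  RMSE 1.0838  MAE 0.6262  MAPE 2.16%  MASE 0.2001  R2 0.9844

clim <- monthly_climatology(series)
proj <- project(fit, clim, scenario_spec("pessimistic", seed = 7),
                "2022-01-01", "2022-12-31", init_hi = tail(hs$hi, 6))
head(round(category_distribution(proj), 2))
```

The metrics line reads: on the held-out year the forest estimates 3-hourly
HI with ~1.1 °C RMSE, explains 98 % of variance, and makes one fifth of the
persistence benchmark's absolute error (MASE 0.20). `proj` holds the
recursive trajectory with per-step empirical interval bounds and risk
categories; the category distribution summarises projected heat-stress
exposure.

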