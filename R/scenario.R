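#' Build the complete 3-hourly future calendar grid
#'
#' One row per synoptic hour between the two dates inclusive, with calendar
#' features (hour, day, month) and one-hot season indicators encoded
#' consistently with the training feature dictionary.
#'
#' @param start,end calendar dates.
#' @return data frame with `timestamp` and calendar/season columns.
#' @examples
#' nrow(build_future_grid("2024-01-01", "2027-12-31"))  # 11688
#' @export
build_future_grid <- function(start, end) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (is.na(start) || is.na(end)) stop("invalid date")
  if (end < start) stop("end precedes start")
  days <- seq(start, end, by = "day")
  timestamp <- as.POSIXct(rep(days, each = length(SYNOPTIC_HOURS)),
                          tz = "UTC") +
    rep(SYNOPTIC_HOURS, times = length(days)) * 3600
  cbind(data.frame(timestamp = timestamp), calendar_features(timestamp))
}

#' Monthly climatology of temperature and humidity
#'
#' Per-calendar-month arithmetic means over the historical record. All 12
#' months must be represented.
#'
#' @param series a `climate_series`.
#' @return a `climatology` data frame: `month`, `temperature`,
#'   `relative_humidity`.
#' @export
monthly_climatology <- function(series) {
  month <- as.POSIXlt(series$timestamp, tz = "UTC")$mon + 1L
  present <- sort(unique(month))
  if (!identical(present, 1:12))
    stop("climatology requires every calendar month; missing: ",
         paste(setdiff(1:12, present), collapse = ", "))
  out <- data.frame(
    month = 1:12,
    temperature = as.numeric(tapply(series$temperature, month, mean)),
    relative_humidity = as.numeric(tapply(series$relative_humidity, month,
                                          mean))
  )
  class(out) <- c("climatology", "data.frame")
  out
}

SCENARIO_PRESETS <- list(
  optimistic = list(delta_t = -0.5, delta_rh = -2, noise_level = "low"),
  moderate = list(delta_t = 0, delta_rh = 0, noise_level = "moderate"),
  pessimistic = list(delta_t = 1.0, delta_rh = 3, noise_level = "elevated")
)
NOISE_LEVELS <- list(low = c(temp = 0.5, rh = 2),
                     moderate = c(temp = 1.0, rh = 4),
                     elevated = c(temp = 1.5, rh = 6))

#' Specify a climatological scenario
#'
#' Presets pin the deterministic shifts of the three named scenarios:
#' optimistic (-0.5 deg C, -2 pp, low noise), moderate (0, 0, moderate
#' noise), pessimistic (+1.0 deg C, +3 pp, elevated noise). The noise
#' levels translate to Gaussian SDs of 0.5/1.0/1.5 deg C for temperature
#' and 2/4/6 pp for humidity; explicit SDs override them.
#'
#' @param name `"optimistic"`, `"moderate"`, `"pessimistic"`, or a custom
#'   label (custom labels require explicit shifts).
#' @param delta_t temperature shift, deg C (preset default by name).
#' @param delta_rh humidity shift, percentage points.
#' @param noise_level `"low"`, `"moderate"` or `"elevated"`.
#' @param sd_temp,sd_rh explicit noise SDs overriding `noise_level`.
#' @param seed integer seed; the scenario's weather is drawn once per seed.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(name = "moderate", delta_t = NULL, delta_rh = NULL,
                          noise_level = NULL, sd_temp = NULL, sd_rh = NULL,
                          seed = 1L) {
  preset <- SCENARIO_PRESETS[[name]]
  if (is.null(preset) && (is.null(delta_t) || is.null(delta_rh)))
    stop("custom scenario '", name, "' needs explicit delta_t and delta_rh")
  delta_t <- delta_t %||% preset$delta_t
  delta_rh <- delta_rh %||% preset$delta_rh
  noise_level <- noise_level %||% (preset$noise_level %||% "moderate")
  sds <- NOISE_LEVELS[[noise_level]]
  if (is.null(sds) && (is.null(sd_temp) || is.null(sd_rh)))
    stop("unknown noise level: ", noise_level)
  spec <- list(name = name, delta_t = delta_t, delta_rh = delta_rh,
               noise_level = noise_level,
               sd_temp = sd_temp %||% unname(sds["temp"]),
               sd_rh = sd_rh %||% unname(sds["rh"]),
               seed = as.integer(seed))
  class(spec) <- "scenario_spec"
  spec
}

#' Construct scenario weather on a future grid
#'
#' Expands the monthly climatology as constants within each month, applies
#' the scenario's deterministic shifts, and adds independent Gaussian noise
#' drawn once under the scenario seed. Humidity is clipped to \[0, 100\] %.
#'
#' @param clim a `climatology`.
#' @param grid a future calendar grid from [build_future_grid()].
#' @param spec a `scenario_spec`.
#' @return a `climate_series` on the future grid.
#' @export
apply_scenario <- function(clim, grid, spec) {
  if (!inherits(spec, "scenario_spec")) stop("spec must be a scenario_spec")
  n <- nrow(grid)
  set.seed(spec$seed)
  temp <- clim$temperature[grid$month] + spec$delta_t +
    (if (spec$sd_temp > 0) rnorm(n, 0, spec$sd_temp) else 0)
  rh <- clim$relative_humidity[grid$month] + spec$delta_rh +
    (if (spec$sd_rh > 0) rnorm(n, 0, spec$sd_rh) else 0)
  rh <- pmin(pmax(rh, 0), 100)
  new_climate_series(grid$timestamp, temp, rh)
}

#' Empirical ensemble prediction interval
#'
#' Mean and the empirical 2.5th/97.5th percentiles (linear interpolation of
#' order statistics, [stats::quantile()] type 7) of per-tree predictions.
#'
#' @param tree_predictions numeric vector of B >= 2 ensemble member
#'   predictions, or a matrix with one row per observation and one column
#'   per member.
#' @param level interval level (default 0.95).
#' @return for a vector, `c(mean, lower, upper)`; for a matrix, a data
#'   frame with columns `mean`, `lower`, `upper`.
#' @export
empirical_interval <- function(tree_predictions, level = 0.95) {
  a <- (1 - level) / 2
  if (is.matrix(tree_predictions)) {
    if (ncol(tree_predictions) < 2) stop("need at least 2 ensemble members")
    q <- t(apply(tree_predictions, 1, quantile, probs = c(a, 1 - a),
                 names = FALSE, type = 7))
    return(data.frame(mean = rowMeans(tree_predictions),
                      lower = q[, 1], upper = q[, 2]))
  }
  if (length(tree_predictions) < 2) stop("need at least 2 ensemble members")
  q <- quantile(tree_predictions, probs = c(a, 1 - a), names = FALSE,
                type = 7)
  c(mean = mean(tree_predictions), lower = q[1], upper = q[2])
}

#' Coverage and width of prediction intervals
#'
#' Coverage is the share of observations falling inside their interval,
#' endpoints inclusive; width is the mean of `upper - lower`.
#'
#' @param intervals data frame with `lower` and `upper` columns.
#' @param observed numeric vector aligned with `intervals`.
#' @return list with `coverage_pct` and `mean_width`.
#' @export
interval_calibration <- function(intervals, observed) {
  if (nrow(intervals) != length(observed))
    stop("intervals and observations are misaligned")
  inside <- observed >= intervals$lower & observed <= intervals$upper
  list(coverage_pct = 100 * mean(inside),
       mean_width = mean(intervals$upper - intervals$lower))
}

#' Recursive 3-hour-ahead projection over a future horizon
#'
#' Steps through the future grid one 3-hour step at a time. At each step the
#' lagged Heat Index features are drawn from the concatenation of the six
#' initializing observed values and all previous predictions, the model
#' predicts one step ahead, and the prediction is appended to the lag
#' state. For forest models the per-tree predictions are retained at every
#' step and summarised into empirical 95% intervals; other models report
#' point trajectories only (bounds `NA`).
#'
#' @param model a `heatfit`.
#' @param future a `climate_series` of scenario weather on the complete
#'   3-hourly future grid (e.g. from [apply_scenario()]).
#' @param init_hi the last 6 observed Heat Index values (deg C),
#'   chronological order, immediately preceding the horizon.
#' @param scenario_name label recorded in the result.
#' @param level interval level for forest models.
#' @return a `projection_result` data frame: `timestamp`, `scenario`,
#'   `point`, `lower`, `upper`, `category`.
#' @export
recursive_project <- function(model, future, init_hi,
                              scenario_name = "scenario", level = 0.95) {
  max_lag <- max(model$lags %||% c(1L, 3L, 6L))
  if (length(init_hi) != max_lag)
    stop("init_hi must supply exactly ", max_lag, " values")
  if (nrow(future) > 1 &&
      any(diff(as.numeric(future$timestamp)) != STEP_SECONDS))
    stop("future grid has gaps")
  lags <- model$lags %||% c(1L, 3L, 6L)
  n <- nrow(future)

  fm <- cbind(
    data.frame(timestamp = future$timestamp,
               temperature = future$temperature,
               relative_humidity = future$relative_humidity),
    calendar_features(future$timestamp)
  )
  for (k in lags) fm[[paste0("hi_lag", k)]] <- NA_real_
  class(fm) <- c("feature_matrix", "data.frame")

  is_forest <- model$model == "rfr"
  state <- c(init_hi, numeric(n))
  point <- numeric(n)
  lower <- upper <- rep(NA_real_, n)
  a <- (1 - level) / 2

  if (!is.null(model$predict_fn)) {
    # pluggable predictor (one raw feature row in, one prediction out);
    # used for audits of the lag-state bookkeeping
    for (t in seq_len(n)) {
      row <- fm[t, , drop = FALSE]
      for (i in seq_along(lags))
        row[[paste0("hi_lag", lags[i])]] <- state[t + max_lag - lags[i]]
      point[t] <- model$predict_fn(row)
      state[t + max_lag] <- point[t]
    }
  } else if (is_forest || model$model == "gboost") {
    # pre-scale the static part of the design matrix once; lag columns are
    # filled (scaled) per step
    X <- ml_design(model, fm)
    lag_cols <- match(paste0("hi_lag", lags), colnames(X))
    sc <- model$scaler
    lag_min <- sc$min[paste0("hi_lag", lags)]
    lag_rng <- sc$max[paste0("hi_lag", lags)] - lag_min
    pf <- if (is_forest) pack_forest(model$fit)
    for (t in seq_len(n)) {
      X[t, lag_cols] <- (state[t + max_lag - lags] - lag_min) / lag_rng
      if (is_forest) {
        trees <- predict_packed_row(pf, X[t, ])
        point[t] <- mean(trees)
        q <- quantile(trees, probs = c(a, 1 - a), names = FALSE, type = 7)
        lower[t] <- q[1]
        upper[t] <- q[2]
      } else {
        point[t] <- predict(model$fit,
                            xgboost::xgb.DMatrix(X[t, , drop = FALSE]))
      }
      state[t + max_lag] <- point[t]
    }
  } else if (model$model == "naive") {
    for (t in seq_len(n)) {
      point[t] <- state[t + max_lag - 1L]
      state[t + max_lag] <- point[t]
    }
  } else {
    # linear adapters: dynamic multi-step forecast with the scenario
    # exogenous path (lag state not part of the regression)
    point <- predict(model, fm)
    state[max_lag + seq_len(n)] <- point
  }

  out <- data.frame(timestamp = future$timestamp, scenario = scenario_name,
                    point = point, lower = lower, upper = upper,
                    category = categorize(point))
  class(out) <- c("projection_result", "data.frame")
  out
}

#' Project a fitted estimator under a climatological scenario
#'
#' @param model a fitted `heatfit`.
#' @param ... passed to methods.
#' @export
project <- function(model, ...) UseMethod("project")

#' @describeIn project Convenience wrapper: builds the future grid, applies
#'   the scenario to the supplied climatology, and runs the recursive
#'   projection.
#' @param clim a `climatology` from the historical record.
#' @param spec a `scenario_spec`.
#' @param start,end projection horizon dates.
#' @param init_hi last 6 observed Heat Index values before the horizon.
#' @param level interval level.
#' @export
project.heatfit <- function(model, clim, spec, start, end, init_hi,
                            level = 0.95, ...) {
  grid <- build_future_grid(start, end)
  future <- apply_scenario(clim, grid, spec)
  recursive_project(model, future, init_hi, scenario_name = spec$name,
                    level = level)
}
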