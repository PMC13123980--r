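SEASON_COLS <- paste0("season_", c("winter", "spring", "summer", "autumn"))

lag_vec <- function(x, k) c(rep(NA_real_, k), head(x, -k))

calendar_features <- function(timestamp) {
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  out <- data.frame(
    hour = lt$hour,
    day = lt$mday,
    month = lt$mon + 1L
  )
  season <- assign_season(out$month)
  for (s in levels(season)) out[[paste0("season_", s)]] <-
    as.numeric(season == s)
  out
}

#' Build a leakage-safe feature matrix from a Heat Index series
#'
#' One row per timestamp with exogenous predictors (temperature, relative
#' humidity), calendar integers (hour, day-of-month, month), one-hot season
#' indicators, lagged Heat Index predictors taken strictly from past
#' observations, and the target `hi`. Rows lacking the full lag history
#' (the first `max(lags)` records) are dropped. The series must be
#' gap-free: lags are undefined across gaps.
#'
#' @param series a `heat_index_series` on the complete 3-hourly grid.
#' @param lags integer lags in 3-hour steps (default `c(1, 3, 6)`).
#' @return a `feature_matrix` data frame.
#' @export
build_features <- function(series, lags = c(1L, 3L, 6L)) {
  if (!all(c("hi", "temperature", "relative_humidity") %in% names(series)))
    stop("series must carry temperature, relative_humidity and hi")
  if (nrow(series) > 1 &&
      any(diff(as.numeric(series$timestamp)) != STEP_SECONDS))
    stop("series has gaps or irregular spacing; lags are undefined")
  lags <- sort(as.integer(lags))
  fm <- cbind(
    data.frame(timestamp = series$timestamp),
    data.frame(temperature = series$temperature,
               relative_humidity = series$relative_humidity),
    calendar_features(series$timestamp)
  )
  for (k in lags) fm[[paste0("hi_lag", k)]] <- lag_vec(series$hi, k)
  fm$hi <- series$hi
  fm <- fm[-seq_len(max(lags)), , drop = FALSE]
  rownames(fm) <- NULL
  class(fm) <- c("feature_matrix", "data.frame")
  attr(fm, "lags") <- lags
  fm
}

#' Chronological train/test split
#'
#' Splits a feature matrix at a boundary timestamp: training rows strictly
#' precede the boundary, test rows start at it. The partition is disjoint,
#' exhaustive and time-ordered, so no future information can reach the
#' training side.
#'
#' @param matrix a `feature_matrix` (or any data frame with a `timestamp`
#'   column).
#' @param boundary a date or POSIXct; e.g. `"2022-01-01"` reserves
#'   2022 onwards for testing.
#' @return list with `train` and `test`.
#' @export
chronological_split <- function(matrix, boundary) {
  b <- as.POSIXct(boundary, tz = "UTC")
  if (is.na(b)) stop("invalid boundary")
  ts <- matrix$timestamp
  if (b <= min(ts) || b > max(ts))
    stop("boundary outside the data range")
  train <- matrix[ts < b, , drop = FALSE]
  test <- matrix[ts >= b, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  lapply(list(train = train, test = test), function(x) {
    class(x) <- class(matrix)
    attr(x, "lags") <- attr(matrix, "lags")
    x
  })
}
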