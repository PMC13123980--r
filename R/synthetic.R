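#' Configuration for the synthetic 3-hourly climate generator
#'
#' Defines a Dhaka-like gap-free 3-hourly temperature/relative-humidity
#' process: an annual sinusoid plus a diurnal sinusoid plus stationary AR(1)
#' noise for temperature, and humidity coupled negatively to the temperature
#' anomaly with additive white noise, clipped to \[5, 100\] %.
#'
#' Default moments reproduce the descriptive statistics of the Dhaka record
#' the generator emulates: summer (Jun-Aug) mean temperature near 29.5 deg C,
#' winter (Dec-Feb) mean near 20.7 deg C, and corr(T, RH) near -0.36.
#'
#' @param start_date,end_date calendar dates (coercible via [as.Date()]);
#'   `end_date >= start_date`.
#' @param mean_temp long-run mean temperature, deg C.
#' @param annual_amplitude amplitude of the annual cycle, deg C.
#' @param annual_peak_month calendar month (1-12) in which the annual cycle
#'   peaks (on the 15th).
#' @param diurnal_amplitude amplitude of the diurnal cycle, deg C.
#' @param diurnal_peak_hour hour of day (0-23) at which the diurnal cycle
#'   peaks.
#' @param ar_coefficient AR(1) coefficient of the temperature noise at the
#'   3-hour step, in \[0, 1).
#' @param noise_sd innovation standard deviation of the AR(1) noise, deg C.
#' @param rh_baseline mean relative humidity, %.
#' @param rh_coupling humidity response to the temperature anomaly
#'   (T - mean_temp), % per deg C; negative for the observed inverse
#'   relationship.
#' @param rh_noise_sd white-noise standard deviation of humidity, %.
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @return an object of class `synthetic_config`.
#' @seealso [generate_climate()]
#' @export
synthetic_config <- function(start_date = "2014-01-01",
                             end_date = "2023-12-31",
                             mean_temp = 25.1,
                             annual_amplitude = 5.7,
                             annual_peak_month = 6L,
                             diurnal_amplitude = 3.0,
                             diurnal_peak_hour = 12L,
                             ar_coefficient = 0.8,
                             noise_sd = 1.2,
                             rh_baseline = 75,
                             rh_coupling = -0.6,
                             rh_noise_sd = 8,
                             seed = 1L) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date))
    stop("start_date and end_date must be valid dates")
  if (end_date < start_date)
    stop("end_date must not precede start_date")
  if (noise_sd < 0 || rh_noise_sd < 0)
    stop("noise standard deviations must be non-negative")
  if (ar_coefficient < 0 || ar_coefficient >= 1)
    stop("ar_coefficient must lie in [0, 1)")
  if (!annual_peak_month %in% 1:12)
    stop("annual_peak_month must be in 1..12")
  cfg <- list(
    start_date = start_date, end_date = end_date,
    mean_temp = mean_temp, annual_amplitude = annual_amplitude,
    annual_peak_month = as.integer(annual_peak_month),
    diurnal_amplitude = diurnal_amplitude,
    diurnal_peak_hour = as.integer(diurnal_peak_hour),
    ar_coefficient = ar_coefficient, noise_sd = noise_sd,
    rh_baseline = rh_baseline, rh_coupling = rh_coupling,
    rh_noise_sd = rh_noise_sd, seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  cfg
}

new_climate_series <- function(timestamp, temperature, relative_humidity) {
  out <- data.frame(
    timestamp = timestamp,
    temperature = temperature,
    relative_humidity = relative_humidity
  )
  class(out) <- c("climate_series", "data.frame")
  out
}

#' Generate a synthetic gap-free 3-hourly climate series
#'
#' Produces one record per synoptic hour (00, 03, ..., 21) for every day in
#' the configured range. Temperature is the sum of the configured mean, the
#' annual and diurnal sinusoids, and AR(1) noise initialised at its
#' stationary distribution (no burn-in transient). Relative humidity is
#' `rh_baseline + rh_coupling * (temperature - mean_temp)` plus white noise,
#' clipped to \[5, 100\] %.
#'
#' @param config a [synthetic_config()].
#' @return a `climate_series` data frame with columns `timestamp` (POSIXct,
#'   UTC), `temperature` (deg C) and `relative_humidity` (%).
#' @examples
#' cs <- generate_climate(synthetic_config("2020-01-01", "2020-01-31"))
#' nrow(cs)  # 31 days x 8 records
#' @export
generate_climate <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, as.list(config))
  days <- seq(config$start_date, config$end_date, by = "day")
  n_day <- length(days)
  date <- rep(days, each = length(SYNOPTIC_HOURS))
  hour <- rep(SYNOPTIC_HOURS, times = n_day)
  timestamp <- as.POSIXct(date, tz = "UTC") + hour * 3600
  n <- length(timestamp)

  # fractional day-of-year drives the annual phase; peak on the 15th of the
  # configured month, 365.25-day cycle
  doy <- as.integer(strftime(date, "%j", tz = "UTC")) + hour / 24
  peak_doy <- as.integer(strftime(
    as.Date(sprintf("2001-%02d-15", config$annual_peak_month)), "%j"))
  annual <- config$annual_amplitude *
    cos(2 * pi * (doy - peak_doy) / 365.25)
  diurnal <- config$diurnal_amplitude *
    cos(2 * pi * (hour - config$diurnal_peak_hour) / 24)

  set.seed(config$seed)
  phi <- config$ar_coefficient
  if (config$noise_sd > 0) {
    innov <- rnorm(n, 0, config$noise_sd)
    init <- rnorm(1, 0, config$noise_sd / sqrt(1 - phi^2))
    noise <- as.numeric(stats::filter(innov, phi, method = "recursive",
                                      init = init))
  } else {
    noise <- numeric(n)
  }
  temperature <- config$mean_temp + annual + diurnal + noise

  rh_noise <- if (config$rh_noise_sd > 0) rnorm(n, 0, config$rh_noise_sd)
              else numeric(n)
  rh <- config$rh_baseline +
    config$rh_coupling * (temperature - config$mean_temp) + rh_noise
  rh <- pmin(pmax(rh, 5), 100)

  new_climate_series(timestamp, temperature, rh)
}

series_keys <- function(series) {
  lt <- as.POSIXlt(series$timestamp, tz = "UTC")
  data.frame(year = lt$year + 1900L, month = lt$mon + 1L,
             day = lt$mday, hour = lt$hour)
}

long_pair_from_series <- function(series) {
  k <- series_keys(series)
  list(
    temperature = cbind(k, value = series$temperature),
    relative_humidity = cbind(k, value = series$relative_humidity)
  )
}

wide_from_long <- function(long) {
  hours <- sprintf("%02d", SYNOPTIC_HOURS)
  wide <- unique(long[c("year", "month", "day")])
  wide <- wide[order(wide$year, wide$month, wide$day), , drop = FALSE]
  for (h in seq_along(SYNOPTIC_HOURS)) {
    sub <- long[long$hour == SYNOPTIC_HOURS[h], ]
    idx <- match(paste(wide$year, wide$month, wide$day),
                 paste(sub$year, sub$month, sub$day))
    wide[[hours[h]]] <- sub$value[idx]
  }
  names(wide)[1:3] <- c("Year", "Month", "Day")
  rownames(wide) <- NULL
  wide
}

#' Write a climate series as the wide temperature/humidity fixture pair
#'
#' Writes two CSV tables in the wide synoptic dialect: one row per calendar
#' day keyed by `Year`, `Month`, `Day`, and one value column per synoptic
#' hour (`00`, `03`, ..., `21`); one file for temperature and one for
#' relative humidity. The pair round-trips losslessly through
#' [read_wide_tables()].
#'
#' @param series a non-empty `climate_series`.
#' @param temp_path,rh_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_wide_fixtures <- function(series, temp_path, rh_path) {
  if (!nrow(series)) stop("cannot write fixtures for an empty series")
  pair <- long_pair_from_series(series)
  wt <- wide_from_long(pair$temperature)
  wr <- wide_from_long(pair$relative_humidity)
  for (p in c(temp_path, rh_path)) {
    d <- dirname(p)
    if (!dir.exists(d)) stop("unwritable path: directory does not exist: ", d)
  }
  write.csv(wt, temp_path, row.names = FALSE)
  write.csv(wr, rh_path, row.names = FALSE)
  invisible(c(temp_path, rh_path))
}

#' Inject a structural defect into a raw long-format table pair
#'
#' Produces corrupted raw tables for negative testing of the QC stage:
#' a deleted record (`missing_row`), a duplicated key (`duplicate_key`),
#' or an impossible calendar date such as February 30 (`invalid_date`).
#' The defect position is chosen with the given seed.
#'
#' @param series a non-empty `climate_series`.
#' @param kind one of `"missing_row"`, `"duplicate_key"`, `"invalid_date"`.
#' @param seed integer seed selecting the defect position.
#' @return a list with long-format `temperature` and `relative_humidity`
#'   tables (columns `year`, `month`, `day`, `hour`, `value`), the defect
#'   injected into the temperature table.
#' @export
inject_defects <- function(series, kind = c("missing_row", "duplicate_key",
                                            "invalid_date"), seed = 1L) {
  if (!nrow(series)) stop("series is empty")
  kind <- match.arg(kind)
  pair <- long_pair_from_series(series)
  tt <- pair$temperature
  set.seed(as.integer(seed))
  # keep endpoints so the expected grid span is unchanged
  i <- if (nrow(tt) > 2) sample(2:(nrow(tt) - 1), 1) else 1L
  if (kind == "missing_row") {
    tt <- tt[-i, ]
    pair$relative_humidity <- pair$relative_humidity[-i, ]
  } else if (kind == "duplicate_key") {
    tt <- rbind(tt, tt[i, ])
  } else {
    tt$month[i] <- 2L
    tt$day[i] <- 30L
  }
  rownames(tt) <- NULL
  pair$temperature <- tt
  pair
}
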