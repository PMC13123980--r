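#' The nine Rothfusz regression constants
#'
#' Fixed coefficients of the NWS multiple-regression approximation to
#' Steadman's apparent-temperature table, for temperature in deg F and
#' relative humidity in percent. Not user-configurable.
#'
#' @format named numeric vector of length 9.
#' @export
rothfusz_coefficients <- c(
  c0 = -42.379, c1 = 2.04901523, c2 = 10.14333127, c3 = -0.22475541,
  c4 = -0.00683783, c5 = -0.05481717, c6 = 0.00122874, c7 = 0.00085282,
  c8 = -0.00000199
)

RISK_LEVELS <- c("Normal", "Caution", "ExtremeCaution", "Danger",
                 "ExtremeDanger")
RISK_BREAKS_C <- c(27, 32, 41, 54)

check_rh <- function(rh) {
  if (any(!is.finite(rh)) || any(rh < 0 | rh > 100))
    stop("relative humidity must lie in [0, 100]")
  invisible(rh)
}

#' Simplified Steadman estimate of the Heat Index
#'
#' The linear preliminary formula
#' `0.5 * (T + 61 + (T - 68) * 1.2 + RH * 0.094)`, temperature in deg F.
#' This cheap estimate decides whether the full Rothfusz regression is
#' needed.
#'
#' @param temp_f air temperature, deg F.
#' @param rh relative humidity, % (in \[0, 100\]).
#' @return heat index estimate, deg F.
#' @export
hi_simple <- function(temp_f, rh) {
  check_rh(rh)
  0.5 * (temp_f + 61 + (temp_f - 68) * 1.2 + rh * 0.094)
}

#' Stage-1 preliminary Heat Index
#'
#' Two conventions are supported. Mode `"average"` averages the simplified
#' Steadman value with the air temperature; mode `"nws"` uses the
#' simplified value directly (the canonical NWS practice, where the simple
#' formula is itself the average). The preliminary value selects the
#' computation branch: below 80 deg F it is the final answer, at or above
#' 80 deg F the Rothfusz regression takes over.
#'
#' @inheritParams hi_simple
#' @param mode `"average"` (default) or `"nws"`.
#' @return preliminary heat index, deg F.
#' @export
preliminary_hi <- function(temp_f, rh, mode = c("average", "nws")) {
  mode <- match.arg(mode)
  s <- hi_simple(temp_f, rh)
  if (mode == "average") (s + temp_f) / 2 else s
}

#' Full Rothfusz regression
#'
#' Nine-term polynomial in temperature (deg F) and relative humidity (%).
#' Intended for preliminary values of 80 deg F and above; the branch is
#' enforced by [heat_index_celsius()], not here.
#'
#' @inheritParams hi_simple
#' @return heat index, deg F.
#' @export
hi_rothfusz <- function(temp_f, rh) {
  cf <- unname(rothfusz_coefficients)
  T <- temp_f
  cf[1] + cf[2] * T + cf[3] * rh + cf[4] * T * rh +
    cf[5] * T^2 + cf[6] * rh^2 + cf[7] * T^2 * rh +
    cf[8] * T * rh^2 + cf[9] * T^2 * rh^2
}

#' Low-humidity adjustment to the Rothfusz value
#'
#' For RH < 13% and 80 <= T <= 112 deg F the quantity
#' `((13 - RH) / 4) * sqrt((17 - |T - 95|) / 17)` is subtracted from the
#' regression value. Returns the (non-negative) magnitude to subtract;
#' zero outside the condition window.
#'
#' @inheritParams hi_simple
#' @return adjustment magnitude, deg F.
#' @export
adjustment_low_humidity <- function(temp_f, rh) {
  # radicand clamped at 0: outside the window the branch is unused, but
  # vectorized evaluation must not emit NaN warnings
  adj <- ((13 - rh) / 4) * sqrt(pmax(17 - abs(temp_f - 95), 0) / 17)
  ifelse(rh < 13 & temp_f >= 80 & temp_f <= 112, adj, 0)
}

#' High-humidity adjustment to the Rothfusz value
#'
#' For RH > 85% and 80 <= T <= 87 deg F the quantity
#' `((RH - 85) / 10) * ((87 - T) / 5)` is added to the regression value.
#' Zero outside the condition window.
#'
#' @inheritParams hi_simple
#' @return adjustment to add, deg F.
#' @export
adjustment_high_humidity <- function(temp_f, rh) {
  adj <- ((rh - 85) / 10) * ((87 - temp_f) / 5)
  ifelse(rh > 85 & temp_f >= 80 & temp_f <= 87, adj, 0)
}

#' Two-stage NWS Heat Index in Celsius
#'
#' Converts temperature to deg F, evaluates the Stage-1 preliminary
#' estimate, and where that preliminary reaches 80 deg F replaces it by the
#' full Rothfusz regression with the applicable humidity adjustment
#' (subtracted below 13% RH, added above 85% RH, within their temperature
#' windows). The result is converted back to deg C. All arithmetic is in
#' double precision with no intermediate rounding. Vectorized.
#'
#' @param temp_c air temperature, deg C.
#' @param rh relative humidity, % (in \[0, 100\]).
#' @param mode Stage-1 convention, see [preliminary_hi()].
#' @return heat index, deg C.
#' @examples
#' heat_index_celsius(32.2, 70)  # Rothfusz branch, about 41 deg C
#' heat_index_celsius(21.1, 50)  # simple branch
#' @export
heat_index_celsius <- function(temp_c, rh, mode = c("average", "nws")) {
  mode <- match.arg(mode)
  if (any(!is.finite(temp_c))) stop("temperature must be finite")
  check_rh(rh)
  temp_f <- celsius_to_fahrenheit(temp_c)
  prelim <- preliminary_hi(temp_f, rh, mode)
  hi_f <- prelim
  hot <- prelim >= 80
  if (any(hot)) {
    tf <- temp_f[hot]
    rh_h <- rh[hot]
    hi_f[hot] <- hi_rothfusz(tf, rh_h) -
      adjustment_low_humidity(tf, rh_h) +
      adjustment_high_humidity(tf, rh_h)
  }
  unname(fahrenheit_to_celsius(hi_f))
}

#' Classify a Heat Index value into an NWS risk category
#'
#' Lower-inclusive, upper-exclusive bins in deg C: Normal below 27, Caution
#' \[27, 32), ExtremeCaution \[32, 41), Danger \[41, 54), ExtremeDanger from
#' 54 up. Every finite value maps to exactly one category.
#'
#' @param hi heat index values, deg C; must be finite.
#' @return factor with the five risk levels.
#' @export
categorize <- function(hi) {
  if (any(!is.finite(hi))) stop("heat index must be finite")
  cut(hi, breaks = c(-Inf, RISK_BREAKS_C, Inf), labels = RISK_LEVELS,
      right = FALSE)
}

#' Augment a climate series with Heat Index and risk category
#'
#' @param series a `climate_series`.
#' @param mode Stage-1 convention, see [preliminary_hi()].
#' @return a `heat_index_series`: the input plus `hi` (deg C) and
#'   `category` columns.
#' @export
heat_index <- function(series, mode = c("average", "nws")) {
  mode <- match.arg(mode)
  series$hi <- heat_index_celsius(series$temperature,
                                  series$relative_humidity, mode)
  series$category <- categorize(series$hi)
  class(series) <- unique(c("heat_index_series", class(series)))
  series
}
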