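HOUR_COLS <- sprintf("%02d", c(0, 3, 6, 9, 12, 15, 18, 21))

read_wide_one <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX requires the 'readxl' package")
    wide <- as.data.frame(readxl::read_excel(path))
  } else {
    wide <- read.csv(path, check.names = FALSE)
  }
  names(wide) <- sub("^[Xx]", "", names(wide))
  # hour columns may come in as "0"/"3"/... or "00"/"03"/...
  nm <- names(wide)
  num <- suppressWarnings(as.integer(nm))
  names(wide)[!is.na(num)] <- sprintf("%02d", num[!is.na(num)])
  need <- c("Year", "Month", "Day", HOUR_COLS)
  missing_cols <- setdiff(need, names(wide))
  if (length(missing_cols))
    stop("malformed wide table ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  wide
}

wide_to_long <- function(wide, path) {
  n <- nrow(wide)
  long <- data.frame(
    year = rep(as.integer(wide$Year), times = length(HOUR_COLS)),
    month = rep(as.integer(wide$Month), times = length(HOUR_COLS)),
    day = rep(as.integer(wide$Day), times = length(HOUR_COLS)),
    hour = rep(as.integer(HOUR_COLS), each = n),
    value = unlist(wide[HOUR_COLS], use.names = FALSE),
    row = rep(seq_len(n), times = length(HOUR_COLS))
  )
  validate_dates(long, path)
  long <- long[!is.na(long$value), ]  # empty cells = absent observations
  long <- long[order(long$year, long$month, long$day, long$hour), ]
  rownames(long) <- NULL
  long[c("year", "month", "day", "hour")] <-
    lapply(long[c("year", "month", "day", "hour")], as.integer)
  long$row <- NULL
  long
}

validate_dates <- function(long, origin = "table") {
  d <- strict_date(long$year, long$month, long$day)
  bad <- which(is.na(d))
  if (length(bad)) {
    b <- long[bad[1], ]
    stop("invalid calendar date in ", origin, " at data row ", b$row %||% bad[1],
         ": ", b$year, "-", b$month, "-", b$day)
  }
  invisible(d)
}

# strict date parse: reject Feb 30 and friends by verifying the components
# round-trip through as.Date
strict_date <- function(year, month, day) {
  d <- suppressWarnings(as.Date(sprintf("%04d-%02d-%02d", year, month, day)))
  lt <- as.POSIXlt(d)
  bad <- !is.na(d) &
    (lt$year + 1900L != year | lt$mon + 1L != month | lt$mday != day)
  d[bad] <- NA
  d
}

#' Read the wide temperature/humidity table pair into long format
#'
#' Reads the wide synoptic dialect (rows keyed by `Year`/`Month`/`Day`,
#' one value column per synoptic hour) from CSV or XLSX, reshapes each
#' table to one record per (year, month, day, hour) key, and applies
#' strict calendar-date validation (February 30 and similar are rejected).
#'
#' @param temp_path,rh_path paths to the temperature and relative-humidity
#'   wide tables.
#' @return a list with long `temperature` and `relative_humidity` tables
#'   (columns `year`, `month`, `day`, `hour`, `value`).
#' @seealso [merge_long()], [write_wide_fixtures()]
#' @export
read_wide_tables <- function(temp_path, rh_path) {
  list(
    temperature = wide_to_long(read_wide_one(temp_path), temp_path),
    relative_humidity = wide_to_long(read_wide_one(rh_path), rh_path)
  )
}

key_string <- function(tab) paste(tab$year, tab$month, tab$day, tab$hour)

#' Merge long temperature and humidity tables into a climate series
#'
#' Inner-joins the two tables by the (year, month, day, hour) key, builds a
#' standardized POSIXct (UTC) date-time index, and records keys present in
#' only one table in the `"unmatched"` attribute. Duplicate keys in either
#' table are an error, as is an empty overlap.
#'
#' @param temp_long,rh_long long tables as returned by [read_wide_tables()]
#'   (either element order; the merge is symmetric).
#' @return a `climate_series` ordered by timestamp, with attribute
#'   `"unmatched"` listing keys absent from one side.
#' @export
merge_long <- function(temp_long, rh_long) {
  for (nm in list(list("temperature", temp_long),
                  list("relative_humidity", rh_long))) {
    tab <- nm[[2]]
    d <- strict_date(tab$year, tab$month, tab$day)
    if (anyNA(d)) {
      b <- tab[which(is.na(d))[1], ]
      stop("invalid calendar date in ", nm[[1]], " table: ",
           b$year, "-", b$month, "-", b$day)
    }
    k <- key_string(tab)
    if (anyDuplicated(k))
      stop("duplicate key(s) in ", nm[[1]], " table: ",
           k[duplicated(k)][1])
  }
  kt <- key_string(temp_long)
  kr <- key_string(rh_long)
  common <- intersect(kt, kr)
  if (!length(common)) stop("zero key overlap between the two tables")
  unmatched <- c(setdiff(kt, kr), setdiff(kr, kt))
  tt <- temp_long[match(common, kt), ]
  rr <- rh_long[match(common, kr), ]
  date <- strict_date(tt$year, tt$month, tt$day)
  if (anyNA(date)) {
    b <- tt[which(is.na(date))[1], ]
    stop("invalid calendar date: ", b$year, "-", b$month, "-", b$day)
  }
  timestamp <- as.POSIXct(date, tz = "UTC") + tt$hour * 3600
  out <- new_climate_series(timestamp, tt$value, rr$value)
  out <- out[order(out$timestamp), ]
  rownames(out) <- NULL
  class(out) <- c("climate_series", "data.frame")
  attr(out, "unmatched") <- unmatched
  out
}

#' Check continuity of the 3-hourly grid
#'
#' Lists every expected-but-absent 3-hourly timestamp between the first and
#' last record. Purely descriptive: nothing is modified or removed.
#'
#' @param series a `climate_series`.
#' @return a list of class `qc_report` with `n_records`,
#'   `n_missing_timestamps` and the `missing_timestamps` themselves.
#' @export
validate_continuity <- function(series) {
  if (!nrow(series)) stop("series is empty")
  expected <- seq(min(series$timestamp), max(series$timestamp),
                  by = STEP_SECONDS)
  missing <- expected[!expected %in% series$timestamp]
  out <- list(
    n_records = nrow(series),
    n_missing_timestamps = length(missing),
    missing_timestamps = missing
  )
  class(out) <- "qc_report"
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat("3-hourly grid QC:", x$n_records, "records,",
      x$n_missing_timestamps, "missing timestamp(s)\n")
  invisible(x)
}

#' Flag outliers by the interquartile-range rule
#'
#' Flags, per variable, values outside \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\] with
#' quartiles computed by linear interpolation of order statistics
#' ([stats::quantile()] type 7). Flags are descriptive only; no value is
#' ever removed or altered.
#'
#' @param series a `climate_series` with at least 4 records.
#' @param k fence multiplier (default 1.5).
#' @return a data frame of flags: `timestamp`, `variable`, `value`.
#' @export
flag_outliers_iqr <- function(series, k = 1.5) {
  if (nrow(series) < 4) stop("need at least 4 records for IQR flagging")
  flags <- lapply(c("temperature", "relative_humidity"), function(v) {
    x <- series[[v]]
    q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    out <- x < q[1] - k * iqr | x > q[2] + k * iqr
    data.frame(timestamp = series$timestamp[out],
               variable = rep(v, sum(out)), value = x[out])
  })
  do.call(rbind, flags)
}

#' Map calendar month to meteorological season
#'
#' Standard meteorological quarters: winter = Dec-Feb, spring = Mar-May,
#' summer = Jun-Aug, autumn = Sep-Nov. The mapping is configurable.
#'
#' @param month integer month(s) in 1..12.
#' @param mapping a length-12 character vector giving the season of each
#'   month, January first.
#' @return factor with levels winter, spring, summer, autumn.
#' @export
assign_season <- function(month,
                          mapping = c("winter", "winter", "spring", "spring",
                                      "spring", "summer", "summer", "summer",
                                      "autumn", "autumn", "autumn", "winter")) {
  month <- as.integer(month)
  if (any(is.na(month)) || any(month < 1 | month > 12))
    stop("month must be an integer in 1..12")
  factor(mapping[month], levels = c("winter", "spring", "summer", "autumn"))
}

#' Min-max scaling fitted on the training partition
#'
#' Column ranges are learned from `fit_on` only; training values map into
#' \[0, 1\] and out-of-range application values extrapolate linearly beyond
#' it, so no test-period information leaks into the transform.
#'
#' @param fit_on numeric data frame whose columns define the ranges.
#' @param apply_to data frame to transform (defaults to `fit_on`).
#' @return list with `scaled` (transformed `apply_to`), and the fitted
#'   per-column `min` and `max`.
#' @export
minmax_scale <- function(fit_on, apply_to = fit_on) {
  if (!nrow(fit_on)) stop("fit set is empty")
  mins <- vapply(fit_on, min, numeric(1))
  maxs <- vapply(fit_on, max, numeric(1))
  const <- names(fit_on)[maxs - mins == 0]
  if (length(const))
    stop("constant column(s) cannot be min-max scaled: ",
         paste(const, collapse = ", "))
  scaled <- apply_to
  for (j in names(fit_on))
    scaled[[j]] <- (apply_to[[j]] - mins[j]) / (maxs[j] - mins[j])
  list(scaled = scaled, min = mins, max = maxs)
}

#' Variance inflation factors
#'
#' VIF of feature j is 1 / (1 - R^2_j) from the least-squares regression of
#' feature j on all other features. Perfectly collinear columns yield `Inf`
#' rather than an error.
#'
#' @param features numeric data frame with at least two columns and more
#'   rows than columns.
#' @return named numeric vector of VIFs.
#' @export
compute_vif <- function(features) {
  features <- as.data.frame(features)
  p <- ncol(features)
  if (p < 2) stop("need at least two features")
  if (nrow(features) <= p) stop("need more rows than features")
  vifs <- vapply(seq_len(p), function(j) {
    y <- features[[j]]
    X <- as.matrix(features[-j])
    fit <- lm.fit(cbind(1, X), y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vifs) <- names(features)
  vifs
}
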