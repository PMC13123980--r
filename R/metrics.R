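#' Accuracy metrics for conditional Heat Index estimation
#'
#' Computes MSE, RMSE, MAE, MAPE (in percent), MASE and R-squared. The MASE
#' denominator is the in-sample mean absolute error of the seasonal-naive
#' benchmark at lag `m` on the observed series:
#' `mean(|y_j - y_(j-m)|)` over `j = m+1, ..., n`, with `m = 1`
#' corresponding to 3-hour persistence on the synoptic grid.
#'
#' @param y observed values.
#' @param yhat predicted values, same length. Leading steps where a
#'   forecast is undefined (e.g. the first persistence step) may be `NA`;
#'   such pairs are excluded from scoring while the benchmark denominator
#'   still uses the full observed series, so the in-sample persistence
#'   forecast has MASE exactly 1.
#' @param m benchmark lag in steps (default 1, the persistence forecast).
#' @return a list of class `metrics_report` with fields `mse`, `rmse`,
#'   `mae`, `mape`, `mase`, `r2`, `n` (scored pairs), `m`. If any scored
#'   `y` is zero, `mape` is `NA` with a warning rather than an error.
#' @export
compute_metrics <- function(y, yhat, m = 1L) {
  if (length(y) != length(yhat)) stop("y and yhat differ in length")
  if (length(y) < 2) stop("need at least two observations")
  if (any(!is.finite(y))) stop("observations must be finite")
  scored <- !is.na(yhat)
  if (any(!is.finite(yhat[scored]))) stop("predictions must be finite")
  if (sum(scored) < 2) stop("need at least two scored pairs")
  n_full <- length(y)
  ys <- y[scored]
  e <- ys - yhat[scored]
  mse <- mean(e^2)
  mae <- mean(abs(e))
  mape <- if (any(ys == 0)) {
    warning("y contains zeros; MAPE reported as NA")
    NA_real_
  } else mean(abs(e / ys)) * 100
  denom <- mean(abs(y[(m + 1):n_full] - y[1:(n_full - m)]))
  if (denom == 0)
    stop("MASE undefined: naive benchmark has zero error (constant series)")
  mase <- mae / denom
  r2 <- 1 - sum(e^2) / sum((ys - mean(ys))^2)
  structure(list(mse = mse, rmse = sqrt(mse), mae = mae, mape = mape,
                 mase = mase, r2 = r2, n = sum(scored), m = as.integer(m)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "n=%d  MSE %.4f  RMSE %.4f  MAE %.4f  MAPE %s  MASE %.4f  R2 %.4f\n",
    x$n, x$mse, x$rmse, x$mae,
    if (is.na(x$mape)) "NA" else sprintf("%.2f%%", x$mape), x$mase, x$r2))
  invisible(x)
}

#' Naive persistence forecast
#'
#' The no-change benchmark: the forecast at step t is the observation at
#' t - 1 (one 3-hour step). The first step has no forecast and is excluded
#' from scoring.
#'
#' @param y observed series, length >= 2.
#' @return numeric vector of the same length; first element `NA`.
#' @export
naive_persistence <- function(y) {
  if (length(y) < 2) stop("need at least two observations")
  c(NA_real_, y[-length(y)])
}

#' Share of records per heat-risk category
#'
#' @param x a `heat_index_series`, a `projection_result`, a factor of risk
#'   categories, or numeric Heat Index values in deg C.
#' @return named numeric vector of percentages over the five categories
#'   (sums to 100).
#' @export
category_distribution <- function(x) {
  cats <- if (is.factor(x)) x
    else if (is.numeric(x)) categorize(x)
    else if (!is.null(x$category)) x$category
    else if (!is.null(x$point)) categorize(x$point)
    else if (!is.null(x$hi)) categorize(x$hi)
    else stop("cannot extract risk categories from input")
  if (!length(cats)) stop("empty input")
  counts <- table(factor(cats, levels = RISK_LEVELS))
  setNames(100 * as.numeric(counts) / length(cats), RISK_LEVELS)
}
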