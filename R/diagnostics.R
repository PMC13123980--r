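#' Durbin-Watson statistic for serial correlation
#'
#' `sum(diff(e)^2) / sum(e^2)`. Values near 2 indicate no first-order serial
#' correlation; below 1, strong positive autocorrelation (approximately
#' `2 * (1 - rho)` for AR(1) residuals); near 4, strong negative
#' autocorrelation.
#'
#' @param residuals numeric residual vector, length >= 2, not all zero.
#' @return the statistic.
#' @export
durbin_watson <- function(residuals) {
  if (length(residuals) < 2) stop("need at least two residuals")
  if (all(residuals == 0)) stop("all-zero residuals")
  sum(diff(residuals)^2) / sum(residuals^2)
}

#' Breusch-Pagan test for heteroscedasticity
#'
#' Koenker's studentized LM form: `n * R^2` from the auxiliary regression of
#' squared residuals on the given regressors, referred to a chi-squared
#' distribution with k degrees of freedom (k = number of regressors).
#'
#' @param residuals numeric residual vector.
#' @param regressors numeric vector, matrix or data frame of auxiliary
#'   regressors (without intercept; one is added). Fitted values are the
#'   conventional single-regressor choice.
#' @return list with `statistic`, `df` and `p_value`.
#' @export
breusch_pagan <- function(residuals, regressors) {
  X <- as.matrix(as.data.frame(regressors))
  n <- length(residuals)
  k <- ncol(X)
  if (n <= k) stop("need more observations than regressors")
  if (any(apply(X, 2, function(c) length(unique(c)) == 1L)))
    stop("constant regressor column in auxiliary regression")
  Z <- cbind(1, X)
  if (qr(Z)$rank < ncol(Z)) stop("rank-deficient auxiliary regressors")
  u2 <- residuals^2
  fit <- lm.fit(Z, u2)
  r2 <- 1 - sum(fit$residuals^2) / sum((u2 - mean(u2))^2)
  stat <- n * r2
  list(statistic = stat, df = k,
       p_value = pchisq(stat, df = k, lower.tail = FALSE))
}
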