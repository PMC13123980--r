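MODEL_REGISTRY <- c("naive", "arimax", "sarimax", "rfr", "gboost")

# continuous predictors scaled for the machine-learning adapters; one-hot
# season indicators pass through unscaled
ml_scaled_cols <- function(fm) {
  c("temperature", "relative_humidity", "hour", "day", "month",
    grep("^hi_lag", names(fm), value = TRUE))
}
ml_feature_cols <- function(fm) c(ml_scaled_cols(fm), SEASON_COLS)

# exogenous regressors for the linear adapters: raw values, winter as the
# season baseline, calendar integers excluded
LINEAR_XREG <- c("temperature", "relative_humidity",
                 "season_spring", "season_summer", "season_autumn")

ml_design <- function(object, fm) {
  cols <- object$feature_names
  sc <- object$scaler
  X <- fm[cols]
  for (j in names(sc$min))
    X[[j]] <- (X[[j]] - sc$min[j]) / (sc$max[j] - sc$min[j])
  as.matrix(X)
}

default_params <- function(model) {
  switch(model,
    rfr = list(ntree = 300, nodesize = 5),
    gboost = list(nrounds = 500, learning_rate = 0.05, max_depth = 6,
                  early_stopping_rounds = 20, validation_fraction = 0.1),
    arimax = list(order = c(2, 0, 2)),
    sarimax = list(order = c(1, 0, 1), seasonal_order = c(1, 0, 1),
                   seasonal_period = 8),
    list()
  )
}

#' Fit a conditional Heat Index estimator
#'
#' The single entry point to the model registry. Fits one of
#' \describe{
#'   \item{`naive`}{persistence baseline: the prediction is `hi_lag1`, the
#'     observation 3 hours earlier.}
#'   \item{`arimax`}{ARMA errors with exogenous regressors via
#'     [stats::arima()]; default order (2,0,2), regressors = raw
#'     temperature, humidity and season indicators.}
#'   \item{`sarimax`}{seasonal ARIMA with exogenous regressors; default
#'     (1,0,1)(1,0,1) with period 8 (the daily cycle on the 3-hourly
#'     grid).}
#'   \item{`rfr`}{random forest via \pkg{randomForest}; 300 trees,
#'     square-root feature subsampling; per-tree predictions are retained
#'     for empirical prediction intervals.}
#'   \item{`gboost`}{gradient boosting via \pkg{xgboost}; 500 rounds,
#'     learning rate 0.05, early stopping on a chronological tail slice of
#'     the training data.}
#' }
#' Machine-learning adapters receive min-max-scaled inputs with ranges
#' fitted on the training rows only; statistical adapters receive raw
#' values. Fitting is deterministic given `seed`.
#'
#' @param train a `feature_matrix` from [build_features()] (training rows
#'   only).
#' @param model registry name: `"naive"`, `"arimax"`, `"sarimax"`, `"rfr"`
#'   or `"gboost"`.
#' @param params named list overriding the model's default hyperparameters.
#' @param seed integer seed recorded in the fit and used for all
#'   stochastic components.
#' @return an object of class `heatfit`.
#' @seealso [predict.heatfit()], [expanding_window_cv()], [project()]
#' @export
heatfit <- function(train, model = c("rfr", "arimax", "sarimax", "gboost",
                                     "naive"),
                    params = list(), seed = 1L) {
  model <- match.arg(model)
  if (!nrow(train)) stop("training matrix is empty")
  stopifnot(is.list(params))
  params <- modifyList(default_params(model), params)
  seed <- as.integer(seed)
  set.seed(seed)
  y <- train$hi

  object <- list(model = model, params = params, seed = seed,
                 n_train = nrow(train),
                 train_range = range(train$timestamp),
                 lags = attr(train, "lags"))

  if (model == "naive") {
    object$fit <- NULL
  } else if (model %in% c("arimax", "sarimax")) {
    X <- as.matrix(train[LINEAR_XREG])
    seasonal <- if (model == "sarimax")
      list(order = params$seasonal_order, period = params$seasonal_period)
    else list(order = c(0L, 0L, 0L))
    fit <- arima(y, order = params$order, seasonal = seasonal, xreg = X,
                 method = params$method %||% "CSS")
    object$fit <- fit
    object$xreg_names <- LINEAR_XREG
    object$train_y <- y
    object$train_xreg <- X
  } else {
    cols <- ml_feature_cols(train)
    # like minmax_scale() but tolerant of constant columns (possible in
    # short CV training windows, e.g. a single calendar month): these map
    # to 0 rather than erroring
    sc_cols <- train[ml_scaled_cols(train)]
    mins <- vapply(sc_cols, min, numeric(1))
    maxs <- vapply(sc_cols, max, numeric(1))
    maxs[maxs == mins] <- mins[maxs == mins] + 1
    object$scaler <- list(min = mins, max = maxs)
    object$feature_names <- cols
    Xs <- ml_design(object, train)
    if (model == "rfr") {
      object$fit <- randomForest::randomForest(
        x = Xs, y = y, ntree = params$ntree,
        mtry = max(1L, floor(sqrt(ncol(Xs)))),
        nodesize = params$nodesize)
    } else {
      n <- nrow(Xs)
      n_val <- max(1L, floor(params$validation_fraction * n))
      idx_tr <- seq_len(n - n_val)
      idx_va <- (n - n_val + 1L):n
      dtrain <- xgboost::xgb.DMatrix(Xs[idx_tr, , drop = FALSE],
                                     label = y[idx_tr])
      dval <- xgboost::xgb.DMatrix(Xs[idx_va, , drop = FALSE],
                                   label = y[idx_va])
      object$fit <- xgboost::xgb.train(
        params = list(objective = "reg:squarederror",
                      learning_rate = params$learning_rate,
                      max_depth = params$max_depth,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = params$nrounds,
        evals = list(valid = dval),
        early_stopping_rounds = params$early_stopping_rounds,
        verbose = 0)
    }
  }
  class(object) <- "heatfit"
  object$fitted <- predict(object, train)
  object$residuals <- y - object$fitted
  object$train_metrics <- compute_metrics(y, object$fitted)
  object
}

#' Predict from a fitted Heat Index estimator
#'
#' For the machine-learning adapters, `newdata` is transformed with the
#' scaler fitted on the training partition and passed to the underlying
#' model. For the linear adapters, if `newdata` carries the observed target
#' (`hi`) the model is re-filtered over training + new data with
#' coefficients held fixed at their training estimates, yielding one-step
#' (3-hour-ahead) predictions without re-estimation; otherwise a multi-step
#' forecast over `nrow(newdata)` steps with the new exogenous regressors is
#' returned.
#'
#' @param object a `heatfit`.
#' @param newdata a `feature_matrix` (raw, unscaled).
#' @param type `"response"` for point predictions; `"trees"` (forest only)
#'   for the matrix of per-tree predictions, one column per tree, whose
#'   row means equal the point predictions.
#' @param ... unused.
#' @return numeric vector, or a matrix when `type = "trees"`.
#' @export
predict.heatfit <- function(object, newdata, type = c("response", "trees"),
                            ...) {
  type <- match.arg(type)
  if (type == "trees" && object$model != "rfr")
    stop("per-tree predictions are a forest-only feature")
  switch(object$model,
    naive = newdata$hi_lag1,
    rfr = {
      Xs <- ml_design(object, newdata)
      if (type == "trees") {
        ind <- predict(object$fit, Xs, predict.all = TRUE)$individual
        dimnames(ind) <- NULL
        ind
      } else
        unname(predict(object$fit, Xs))
    },
    gboost = {
      Xs <- ml_design(object, newdata)
      unname(predict(object$fit, xgboost::xgb.DMatrix(Xs)))
    },
    {
      # linear adapters
      Xnew <- as.matrix(newdata[object$xreg_names])
      if (!is.null(newdata$hi)) {
        in_train <- newdata$timestamp >= object$train_range[1] &
          newdata$timestamp <= object$train_range[2]
        if (all(in_train)) {
          f <- object$train_y - residuals(object$fit)
          idx <- match(as.numeric(newdata$timestamp),
                       seq(as.numeric(object$train_range[1]),
                           as.numeric(object$train_range[2]),
                           by = STEP_SECONDS))
          return(as.numeric(f[idx]))
        }
        yall <- c(object$train_y, newdata$hi)
        xall <- rbind(object$train_xreg, Xnew)
        p <- object$params
        seasonal <- if (object$model == "sarimax")
          list(order = p$seasonal_order, period = p$seasonal_period)
        else list(order = c(0L, 0L, 0L))
        refit <- arima(yall, order = p$order, seasonal = seasonal,
                       xreg = xall, fixed = coef(object$fit),
                       transform.pars = FALSE, method = "CSS")
        f <- yall - residuals(refit)
        as.numeric(tail(f, nrow(newdata)))
      } else {
        as.numeric(predict(object$fit, n.ahead = nrow(newdata),
                           newxreg = Xnew)$pred)
      }
    }
  )
}

#' @export
print.heatfit <- function(x, ...) {
  cat("Conditional Heat Index estimator\n")
  cat("  model:", x$model, "  seed:", x$seed, "\n")
  cat("  trained on", x$n_train, "records,",
      format(x$train_range[1], tz = "UTC"), "to",
      format(x$train_range[2], tz = "UTC"), "\n")
  cat(sprintf("  training RMSE %.4f degC, R^2 %.4f\n",
              x$train_metrics$rmse, x$train_metrics$r2))
  invisible(x)
}

#' @export
summary.heatfit <- function(object, ...) {
  structure(list(model = object$model, seed = object$seed,
                 n_train = object$n_train, params = object$params,
                 train_metrics = object$train_metrics,
                 coefficients = if (object$model %in% c("arimax", "sarimax"))
                   coef(object$fit)),
            class = "summary.heatfit")
}

#' @export
print.summary.heatfit <- function(x, ...) {
  cat("Model:", x$model, " (seed", paste0(x$seed, ")"), "\n")
  cat("Training records:", x$n_train, "\n")
  m <- x$train_metrics
  cat(sprintf("Training fit: RMSE %.4f, MAE %.4f, R^2 %.4f, MASE %.4f\n",
              m$rmse, m$mae, m$r2, m$mase))
  if (!is.null(x$coefficients)) {
    cat("Coefficients:\n")
    print(x$coefficients)
  }
  invisible(x)
}

#' @export
coef.heatfit <- function(object, ...) {
  if (object$model %in% c("arimax", "sarimax")) coef(object$fit) else NULL
}

#' @export
fitted.heatfit <- function(object, ...) object$fitted

#' @export
residuals.heatfit <- function(object, ...) object$residuals

#' Diagnostic plots for a fitted estimator
#'
#' Observed versus fitted Heat Index on the training rows and the residual
#' series, base graphics.
#'
#' @param x a `heatfit`.
#' @param ... passed to [plot()].
#' @export
plot.heatfit <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  obs <- x$fitted + x$residuals
  plot(obs, x$fitted, xlab = "observed HI (degC)",
       ylab = "fitted HI (degC)", main = paste(x$model, "fit"),
       pch = ".", ...)
  abline(0, 1, col = 2)
  plot(x$residuals, type = "l", xlab = "training step",
       ylab = "residual (degC)", main = "residuals")
  abline(h = 0, col = 2)
  invisible(x)
}
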