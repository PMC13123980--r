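#' Expanding-window time-series cross-validation
#'
#' The training rows are cut chronologically into `folds + 1` equal blocks.
#' Block 1 is the initial training window; blocks 2 to `folds + 1` serve as
#' contiguous, ordered, non-overlapping validation blocks. Fold k trains on
#' every row before its validation block, so training sets strictly expand
#' and never see future data.
#'
#' @param train a `feature_matrix` (training partition).
#' @param model registry name, see [heatfit()].
#' @param folds number of validation folds (default 5).
#' @param params hyperparameter overrides passed to [heatfit()].
#' @param seed integer seed.
#' @return list of class `heatrisk_cv` with `fold_rmse`, `mean_rmse`,
#'   `sd_rmse`, and the fold boundaries.
#' @export
expanding_window_cv <- function(train, model, folds = 5L, params = list(),
                                seed = 1L) {
  n <- nrow(train)
  folds <- as.integer(folds)
  n_blocks <- folds + 1L
  if (n < 2L * n_blocks) stop("too few rows for ", folds, " expanding folds")
  bounds <- floor(seq(0, n, length.out = n_blocks + 1L))
  fold_rmse <- numeric(folds)
  fold_info <- vector("list", folds)
  for (k in seq_len(folds)) {
    val_idx <- (bounds[k + 1L] + 1L):bounds[k + 2L]
    tr_idx <- seq_len(bounds[k + 1L])
    fit <- heatfit(train[tr_idx, , drop = FALSE], model = model,
                   params = params, seed = seed)
    pred <- predict(fit, train[val_idx, , drop = FALSE])
    fold_rmse[k] <- sqrt(mean((train$hi[val_idx] - pred)^2))
    fold_info[[k]] <- list(n_train = length(tr_idx),
                           val_start = val_idx[1], val_end = tail(val_idx, 1))
  }
  structure(list(model = model, folds = folds, fold_rmse = fold_rmse,
                 mean_rmse = mean(fold_rmse), sd_rmse = sd(fold_rmse),
                 fold_info = fold_info, seed = seed),
            class = "heatrisk_cv")
}

#' @export
print.heatrisk_cv <- function(x, ...) {
  cat(sprintf("Expanding-window CV (%s, %d folds): RMSE %.4f +/- %.4f\n",
              x$model, x$folds, x$mean_rmse, x$sd_rmse))
  invisible(x)
}

#' Grid search over hyperparameters by expanding-window CV
#'
#' Evaluates each candidate parameter set with [expanding_window_cv()] on
#' the training partition only and returns the one minimising mean CV RMSE.
#' Ties are broken in favour of the candidate declared first in the grid.
#'
#' @param train a `feature_matrix` (training partition).
#' @param model registry name.
#' @param grid a non-empty list of named parameter lists.
#' @param folds CV folds.
#' @param seed integer seed.
#' @return list with `best_params`, `best_rmse`, and a `results` data frame
#'   of mean/sd RMSE per candidate.
#' @export
grid_search <- function(train, model, grid, folds = 5L, seed = 1L) {
  if (!length(grid)) stop("empty hyperparameter grid")
  res <- lapply(grid, function(p)
    expanding_window_cv(train, model, folds = folds, params = p, seed = seed))
  means <- vapply(res, `[[`, numeric(1), "mean_rmse")
  best <- which.min(means)  # which.min takes the first minimum: tie rule
  list(
    best_params = grid[[best]],
    best_index = best,
    best_rmse = means[best],
    results = data.frame(candidate = seq_along(grid), mean_rmse = means,
                         sd_rmse = vapply(res, `[[`, numeric(1), "sd_rmse"))
  )
}
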