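# build a gap-free heat-index-like series with a prescribed target column
make_series <- function(n, hi, seed = 1) {
  set.seed(seed)
  s <- data.frame(
    timestamp = as.POSIXct("2020-01-01", tz = "UTC") + (seq_len(n) - 1) * 10800,
    temperature = rnorm(n, 25, 3),
    relative_humidity = runif(n, 40, 95),
    hi = hi
  )
  class(s) <- c("heat_index_series", "climate_series", "data.frame")
  s
}

test_that("feature matrix drops burn-in rows and aligns lags to the past", {
  s <- make_series(10, hi = 1:10)
  fm <- build_features(s)
  expect_equal(nrow(fm), 4L)  # 10 - max lag 6
  # hi_lag3 at timestamp t equals hi observed at t - 9 hours
  for (i in seq_len(nrow(fm))) {
    j <- match(fm$timestamp[i] - 3 * 10800, s$timestamp)
    expect_equal(fm$hi_lag3[i], s$hi[j])
  }
  expect_equal(fm$hi_lag1, c(6, 7, 8, 9))
  expect_equal(fm$hi_lag6, c(1, 2, 3, 4))
  # one-hot season columns match the calendar month
  expect_true(all(fm$season_winter == 1))

  gap <- s[-5, ]
  expect_error(build_features(gap), "gaps")
})

test_that("future values never influence earlier feature rows", {
  s <- make_series(50, hi = rnorm(50), seed = 2)
  fm1 <- build_features(s)
  s2 <- s
  s2$hi[40:50] <- rev(s2$hi[40:50])  # permute the future
  s2$temperature[45:50] <- 99
  fm2 <- build_features(s2)
  early <- fm1$timestamp < s$timestamp[34]
  expect_identical(fm1[early, ], fm2[early, ])
})

test_that("chronological split partitions the matrix at the boundary", {
  fm <- small_features()
  sp <- chronological_split(fm, "2021-01-01")
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(fm))
  expect_lt(max(sp$train$timestamp),
            as.POSIXct("2021-01-01", tz = "UTC"))
  expect_gte(min(sp$test$timestamp),
             as.POSIXct("2021-01-01", tz = "UTC"))
  expect_true(all(diff(as.numeric(rbind(sp$train, sp$test)$timestamp)) > 0))
  expect_error(chronological_split(fm, "1990-01-01"), "outside")
  expect_error(chronological_split(fm, "2090-01-01"), "outside")
})

test_that("naive model predicts the 3-hour persistence value", {
  fm <- small_features()
  sp <- chronological_split(fm, "2021-07-01")
  fit <- heatfit(sp$train, "naive")
  expect_equal(predict(fit, sp$test), sp$test$hi_lag1)
})

test_that("forest interpolates a deterministic target almost perfectly", {
  hs <- heat_index(generate_climate(noiseless_config()))
  fm <- build_features(hs)
  fit <- heatfit(fm, "rfr", params = list(ntree = 100), seed = 1)
  expect_gt(fit$train_metrics$r2, 0.99)
})

test_that("fits are deterministic given spec and seed", {
  fm <- small_features()
  sp <- chronological_split(fm, "2021-10-01")
  tr <- sp$train[seq_len(2000), ]
  for (m in c("rfr", "gboost")) {
    p <- if (m == "rfr") list(ntree = 30) else list(nrounds = 40)
    f1 <- heatfit(tr, m, params = p, seed = 99)
    f2 <- heatfit(tr, m, params = p, seed = 99)
    expect_identical(predict(f1, sp$test), predict(f2, sp$test),
                     info = m)
  }
})

test_that("mutating test-period data never changes fitted parameters", {
  fm <- small_features()
  sp <- chronological_split(fm, "2021-07-01")
  probe <- sp$train[1:50, ]

  mutate_test <- function(split) {
    split$test$hi <- split$test$hi + 100
    split$test$temperature <- rev(split$test$temperature)
    split
  }
  sp2 <- mutate_test(sp)

  a1 <- heatfit(sp$train, "arimax")
  a2 <- heatfit(sp2$train, "arimax")
  expect_identical(coef(a1), coef(a2))

  r1 <- heatfit(sp$train, "rfr", params = list(ntree = 30), seed = 5)
  r2 <- heatfit(sp2$train, "rfr", params = list(ntree = 30), seed = 5)
  expect_identical(predict(r1, probe), predict(r2, probe))
})

test_that("forest exposes B per-tree predictions averaging to the point", {
  fm <- small_features()
  tr <- fm[1:1500, ]
  fit <- heatfit(tr, "rfr", params = list(ntree = 40), seed = 3)
  trees <- predict(fit, fm[1501:1600, ], type = "trees")
  expect_equal(ncol(trees), 40L)
  expect_equal(rowMeans(trees), predict(fit, fm[1501:1600, ]),
               tolerance = 1e-10)
  expect_error(predict(heatfit(tr, "naive"), tr, type = "trees"),
               "forest-only")
})

test_that("expanding-window CV trains on strictly growing ordered blocks", {
  fm <- small_features()[1:1000, ]
  cv <- expanding_window_cv(fm, "naive", folds = 5)
  sizes <- vapply(cv$fold_info, `[[`, numeric(1), "n_train")
  expect_true(all(diff(sizes) > 0))
  starts <- vapply(cv$fold_info, `[[`, numeric(1), "val_start")
  ends <- vapply(cv$fold_info, `[[`, numeric(1), "val_end")
  expect_true(all(starts[-1] > ends[-5]))  # disjoint, ordered
  expect_true(all(starts > sizes))         # validation strictly after train
  expect_error(expanding_window_cv(fm[1:10, ], "naive", folds = 6),
               "too few")
})

test_that("CV RMSE of persistence on a random walk matches the innovation SD", {
  set.seed(31)
  n <- 4000
  sigma <- 1.3
  s <- make_series(n, hi = cumsum(rnorm(n, 0, sigma)))
  fm <- build_features(s)
  cv <- expanding_window_cv(fm, "naive", folds = 5)
  # persistence error on a random walk is exactly the innovation
  expect_lt(abs(cv$mean_rmse - sigma), 0.1)
})

test_that("grid search minimises CV error with first-in-grid tie-breaking", {
  fm <- small_features()[1:800, ]
  single <- grid_search(fm, "naive", grid = list(list()), folds = 3)
  expect_equal(single$best_index, 1L)

  tie <- grid_search(fm, "rfr",
                     grid = list(list(ntree = 20), list(ntree = 20)),
                     folds = 3, seed = 2)
  expect_equal(tie$best_index, 1L)  # identical specs: first declared wins

  gs <- grid_search(fm, "rfr",
                    grid = list(list(ntree = 2), list(ntree = 60)),
                    folds = 3, seed = 2)
  expect_equal(gs$best_params$ntree, 60)
  expect_error(grid_search(fm, "rfr", grid = list()), "empty")
})

test_that("every registry model beats persistence on learnable synthetic data", {
  hs <- heat_index(generate_climate(
    synthetic_config("2020-01-01", "2021-12-31", seed = 21)))
  fm <- build_features(hs)
  sp <- chronological_split(fm, "2021-07-01")
  for (m in c("arimax", "sarimax", "rfr", "gboost")) {
    params <- if (m == "rfr") list(ntree = 100) else list()
    fit <- suppressWarnings(heatfit(sp$train, m, params = params, seed = 13))
    met <- compute_metrics(sp$test$hi, predict(fit, sp$test))
    expect_lt(met$mase, 1)
  }
})
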