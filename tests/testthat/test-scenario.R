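test_that("future grid spans the complete 3-hourly horizon", {
  g <- build_future_grid("2024-01-01", "2027-12-31")
  expect_equal(nrow(g), 11688L)  # 1461 days x 8, incl. the 2024 leap day
  expect_equal(nrow(build_future_grid("2025-06-01", "2025-06-01")), 8L)
  july <- g[g$month == 7, ]
  expect_true(all(july$season_summer == 1))
  expect_true(all(july[c("season_winter", "season_spring",
                         "season_autumn")] == 0))
  expect_error(build_future_grid("2025-01-01", "2024-01-01"), "precedes")
})

test_that("monthly climatology averages per calendar month", {
  cs <- generate_climate(synthetic_config(
    "2020-01-01", "2020-12-31", mean_temp = 24, annual_amplitude = 0,
    diurnal_amplitude = 0, noise_sd = 0, rh_baseline = 70, rh_noise_sd = 0))
  clim <- monthly_climatology(cs)
  expect_equal(clim$temperature, rep(24, 12))
  expect_equal(clim$relative_humidity, rep(70, 12))

  # configured annual cycle recovered within Monte-Carlo error
  cfg <- synthetic_config("2016-01-01", "2021-12-31", seed = 12)
  cs2 <- generate_climate(cfg)
  clim2 <- monthly_climatology(cs2)
  lt <- as.POSIXlt(cs2$timestamp, tz = "UTC")
  for (m in c(1, 6, 9)) {
    sel <- lt$mon + 1 == m
    expect_equal(clim2$temperature[m], mean(cs2$temperature[sel]))
  }
  expect_lt(abs(clim2$temperature[6] -
                (cfg$mean_temp + cfg$annual_amplitude * 0.95)), 0.6)

  no_feb <- cs[as.POSIXlt(cs$timestamp, tz = "UTC")$mon + 1 != 2, ]
  expect_error(monthly_climatology(no_feb), "missing: 2")
})

test_that("scenario presets pin the published deterministic shifts", {
  g <- build_future_grid("2024-01-01", "2024-12-31")
  cs <- small_climate()
  clim <- monthly_climatology(cs)
  zero <- function(name) scenario_spec(name, sd_temp = 0, sd_rh = 0,
                                       seed = 4)
  mod <- apply_scenario(clim, g, zero("moderate"))
  # zero-noise moderate repeats the monthly climatology exactly
  expect_equal(mod$temperature, clim$temperature[g$month])
  expect_equal(mod$relative_humidity, clim$relative_humidity[g$month])

  opt <- apply_scenario(clim, g, zero("optimistic"))
  expect_equal(opt$temperature - mod$temperature, rep(-0.5, nrow(g)))
  expect_equal(opt$relative_humidity - mod$relative_humidity,
               rep(-2, nrow(g)))

  pes <- apply_scenario(clim, g, zero("pessimistic"))
  expect_equal(pes$temperature - mod$temperature, rep(1.0, nrow(g)))
  expect_equal(pes$relative_humidity,
               pmin(clim$relative_humidity[g$month] + 3, 100))

  expect_error(scenario_spec("custom_dry"), "explicit")
  custom <- scenario_spec("custom_dry", delta_t = 2, delta_rh = -10,
                          sd_temp = 0, sd_rh = 0)
  expect_equal(apply_scenario(clim, g, custom)$temperature,
               clim$temperature[g$month] + 2)
})

test_that("scenario weather is reproducible and clipped", {
  g <- build_future_grid("2024-01-01", "2024-03-31")
  clim <- monthly_climatology(small_climate())
  s1 <- apply_scenario(clim, g, scenario_spec("pessimistic", seed = 77))
  s2 <- apply_scenario(clim, g, scenario_spec("pessimistic", seed = 77))
  expect_identical(s1, s2)
  clim_wet <- clim
  clim_wet$relative_humidity <- rep(99, 12)
  s3 <- apply_scenario(clim_wet, g, scenario_spec("pessimistic", seed = 1))
  expect_lte(max(s3$relative_humidity), 100)
})

test_that("recursive projection updates the lag state correctly", {
  g <- build_future_grid("2024-01-01", "2024-01-31")
  clim <- monthly_climatology(small_climate())
  future <- apply_scenario(clim, g, scenario_spec("moderate", seed = 2))
  init <- c(20, 21, 22, 23, 24, 25)

  # persistence stub: constant trajectory at the last initializer
  stub_lag1 <- list(predict_fn = function(row) row$hi_lag1,
                    lags = c(1L, 3L, 6L))
  pr <- recursive_project(stub_lag1, future, init)
  expect_equal(pr$point, rep(25, nrow(future)))

  # pass-through stub: trajectory equals the scenario temperature path
  stub_temp <- list(predict_fn = function(row) row$temperature,
                    lags = c(1L, 3L, 6L))
  pr2 <- recursive_project(stub_temp, future, init)
  expect_equal(pr2$point, future$temperature)

  # bookkeeping: at step k > 6 the lag6 feature is the prediction at k - 6
  seen_lag6 <- numeric(0)
  counter <- local({
    k <- 0
    function(row) {
      k <<- k + 1
      seen_lag6[k] <<- row$hi_lag6
      k * 0.5  # deterministic, distinct predictions
    }
  })
  stub_rec <- list(predict_fn = counter, lags = c(1L, 3L, 6L))
  pr3 <- recursive_project(stub_rec, future, init)
  ks <- 7:20
  expect_equal(seen_lag6[ks], pr3$point[ks - 6])
  expect_equal(seen_lag6[1:6], init)

  expect_error(recursive_project(stub_lag1, future, init[1:4]), "exactly 6")
  gap_future <- future[-3, ]
  expect_error(recursive_project(stub_lag1, gap_future, init), "gaps")
})

test_that("empirical interval matches the order-statistic oracle", {
  expect_equal(unname(empirical_interval(rep(3.2, 10))), c(3.2, 3.2, 3.2))

  x <- as.numeric(1:100)
  ei <- empirical_interval(sample(x))
  # brute force: linear interpolation of sorted order statistics at
  # p(n-1)+1
  lower_oracle <- 1 + 0.025 * 99
  upper_oracle <- 1 + 0.975 * 99
  expect_equal(unname(ei), c(mean(x), lower_oracle, upper_oracle))

  m <- matrix(rnorm(200), nrow = 10)
  em <- empirical_interval(m)
  expect_equal(em$mean, rowMeans(m))
  expect_true(all(em$lower <= em$mean & em$mean <= em$upper))
  expect_error(empirical_interval(5), "at least 2")
})

test_that("interval calibration computes inclusive coverage and mean width", {
  y <- rnorm(50)
  iv <- data.frame(lower = y - 1, upper = y + 1)
  cal <- interval_calibration(iv, y)
  expect_equal(cal$coverage_pct, 100)
  expect_equal(cal$mean_width, 2)
  iv2 <- data.frame(lower = y + 1, upper = y + 2)
  expect_equal(interval_calibration(iv2, y)$coverage_pct, 0)
  # boundary observations count as covered
  iv3 <- data.frame(lower = y, upper = y)
  expect_equal(interval_calibration(iv3, y)$coverage_pct, 100)
  expect_error(interval_calibration(iv[1:10, ], y), "misaligned")
})

test_that("forest projections order by scenario severity and bound the point", {
  hs <- small_hi()
  fm <- build_features(hs)
  fit <- heatfit(fm[1:4000, ], "rfr", params = list(ntree = 60), seed = 8)
  clim <- monthly_climatology(small_climate())
  init <- tail(hs$hi, 6)
  means <- sapply(c("optimistic", "moderate", "pessimistic"), function(s) {
    pr <- project(fit, clim, scenario_spec(s, seed = 5), "2024-01-01",
                  "2024-06-30", init)
    expect_true(all(pr$lower <= pr$point + 1e-9 &
                    pr$point <= pr$upper + 1e-9))
    expect_equal(as.character(pr$category), as.character(categorize(pr$point)))
    mean(pr$point)
  })
  expect_lte(means["optimistic"], means["moderate"])
  expect_lte(means["moderate"], means["pessimistic"])

  # full determinism of the projection under a fixed seed
  pr1 <- project(fit, clim, scenario_spec("moderate", seed = 5),
                 "2024-01-01", "2024-01-31", init)
  pr2 <- project(fit, clim, scenario_spec("moderate", seed = 5),
                 "2024-01-01", "2024-01-31", init)
  expect_identical(pr1, pr2)
})
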