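with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

stage_log <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] ", stage), ...)
}

#' Default pipeline configuration
#'
#' @param synthetic a [synthetic_config()] (used when no input files are
#'   given).
#' @param temp_path,rh_path optional wide input tables; when supplied they
#'   replace the synthetic generator.
#' @param split_boundary chronological train/test boundary.
#' @param models registry names to fit and evaluate.
#' @param cv_folds expanding-window CV folds (0 disables CV).
#' @param scenarios scenario names or `scenario_spec` objects.
#' @param horizon_start,horizon_end projection horizon.
#' @param seed master seed; per-component seeds are derived from it.
#' @param out_dir optional output directory for the CSV/JSON artifacts.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            temp_path = NULL, rh_path = NULL,
                            split_boundary = "2022-01-01",
                            models = c("naive", "rfr"),
                            cv_folds = 0L,
                            scenarios = c("optimistic", "moderate",
                                          "pessimistic"),
                            horizon_start = "2024-01-01",
                            horizon_end = "2027-12-31",
                            seed = 1L,
                            out_dir = NULL) {
  cfg <- list(synthetic = synthetic, temp_path = temp_path,
              rh_path = rh_path, split_boundary = split_boundary,
              models = models, cv_folds = as.integer(cv_folds),
              scenarios = scenarios, horizon_start = horizon_start,
              horizon_end = horizon_end, seed = as.integer(seed),
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

# deterministic per-component seeds derived from the master seed; kept
# small so all derived seeds remain valid 32-bit integers
derive_seed <- function(master, offset) (as.integer(master) * 101L + offset) %% 1000003L

#' Run the end-to-end heat-risk pipeline
#'
#' Sequences ingest (or synthetic generation), QC, Heat Index computation,
#' feature building, chronological split, model fitting and evaluation,
#' optional expanding-window CV, residual diagnostics, interval
#' calibration, scenario construction and recursive projection, and report
#' assembly. Deterministic for a fixed master seed; any stage error aborts
#' with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param verbose emit per-stage record counts.
#' @return a list report (class `heatrisk_report`) with QC summary, per
#'   model metrics and diagnostics, calibration, scenario summaries and
#'   the seeds used. When `config$out_dir` is set, the report is also
#'   written as JSON alongside CSVs of the Heat Index series and the
#'   projections, and the paths are returned in `$paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  series <- with_stage("ingest", {
    if (!is.null(config$temp_path) || !is.null(config$rh_path)) {
      if (is.null(config$temp_path) || is.null(config$rh_path))
        stop("both temp_path and rh_path are required")
      pair <- read_wide_tables(config$temp_path, config$rh_path)
      merge_long(pair$temperature, pair$relative_humidity)
    } else {
      cfg <- config$synthetic
      cfg$seed <- derive_seed(seed, 1L)
      generate_climate(cfg)
    }
  })
  stage_log(verbose, "ingest", nrow(series), " records")

  qc <- with_stage("qc", {
    rep <- validate_continuity(series)
    if (rep$n_missing_timestamps > 0)
      stop(rep$n_missing_timestamps, " missing timestamp(s) on the grid")
    flags <- flag_outliers_iqr(series)
    list(n_records = rep$n_records,
         n_missing_timestamps = rep$n_missing_timestamps,
         n_outlier_flags = nrow(flags))
  })
  stage_log(verbose, "qc", qc$n_outlier_flags, " outlier flag(s), none removed")

  hi_series <- with_stage("heat_index", heat_index(series))
  stage_log(verbose, "heat_index", "HI computed; ",
            sum(hi_series$category %in% c("Danger", "ExtremeDanger")),
            " Danger+ records")

  fm <- with_stage("features", build_features(hi_series))
  split <- with_stage("split",
                      chronological_split(fm, config$split_boundary))
  stage_log(verbose, "split", nrow(split$train), " train / ",
            nrow(split$test), " test rows")

  models <- list()
  for (m in config$models) {
    models[[m]] <- with_stage(paste0("fit_", m), {
      fit <- heatfit(split$train, model = m,
                     seed = derive_seed(seed, 2L))
      pred <- predict(fit, split$test)
      metrics <- compute_metrics(split$test$hi, pred)
      res <- split$test$hi - pred
      diag <- list(
        durbin_watson = durbin_watson(res),
        breusch_pagan = breusch_pagan(res, pred)
      )
      cv <- if (config$cv_folds > 0)
        expanding_window_cv(split$train, m, folds = config$cv_folds,
                            seed = derive_seed(seed, 3L))
      calib <- if (m == "rfr") {
        trees <- predict(fit, split$test, type = "trees")
        interval_calibration(empirical_interval(trees), split$test$hi)
      }
      stage_log(verbose, paste0("fit_", m),
                sprintf("test RMSE %.4f, MASE %.4f", metrics$rmse,
                        metrics$mase))
      list(fit = fit, test_metrics = metrics, diagnostics = diag,
           cv = cv, calibration = calib)
    })
  }

  projections <- NULL
  scenario_summary <- NULL
  if (length(config$scenarios) && "rfr" %in% names(models)) {
    clim <- with_stage("climatology", monthly_climatology(series))
    init_hi <- tail(hi_series$hi, 6)
    projections <- list()
    for (s in config$scenarios) {
      projections[[s]] <- with_stage(paste0("project_", s), {
        spec <- if (inherits(s, "scenario_spec")) s
                else scenario_spec(s, seed = derive_seed(seed, 4L))
        project(models$rfr$fit, clim, spec, config$horizon_start,
                config$horizon_end, init_hi)
      })
      stage_log(verbose, paste0("project_", s), nrow(projections[[s]]),
                " projected steps, mean ",
                sprintf("%.2f", mean(projections[[s]]$point)), " degC")
    }
    scenario_summary <- lapply(projections, function(p)
      list(mean_hi = mean(p$point),
           category_pct = as.list(category_distribution(p))))
  }

  report <- with_stage("report", {
    rep <- list(
      seed = seed,
      config = list(split_boundary = config$split_boundary,
                    models = config$models,
                    scenarios = unlist(lapply(config$scenarios, function(s)
                      if (inherits(s, "scenario_spec")) s$name else s)),
                    horizon = c(config$horizon_start, config$horizon_end)),
      qc = qc,
      category_pct_observed = as.list(category_distribution(hi_series)),
      models = lapply(models, function(m) {
        list(test_metrics = unclass(m$test_metrics),
             diagnostics = list(
               durbin_watson = m$diagnostics$durbin_watson,
               breusch_pagan_p = m$diagnostics$breusch_pagan$p_value),
             cv = if (!is.null(m$cv))
               list(fold_rmse = m$cv$fold_rmse,
                    mean_rmse = m$cv$mean_rmse, sd_rmse = m$cv$sd_rmse),
             calibration = m$calibration)
      }),
      scenarios = scenario_summary
    )
    class(rep) <- "heatrisk_report"
    rep
  })

  if (!is.null(config$out_dir)) {
    with_stage("write", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      hi_path <- file.path(config$out_dir, "heat_index_series.csv")
      out <- data.frame(
        timestamp = format(hi_series$timestamp, "%Y-%m-%d %H:%M:%S",
                           tz = "UTC"),
        temperature_c = hi_series$temperature,
        relative_humidity_pct = hi_series$relative_humidity,
        hi_c = hi_series$hi, category = hi_series$category)
      write.csv(out, hi_path, row.names = FALSE)
      proj_path <- NULL
      if (!is.null(projections)) {
        proj_path <- file.path(config$out_dir, "projections.csv")
        all_proj <- do.call(rbind, projections)
        all_proj$timestamp <- format(all_proj$timestamp,
                                     "%Y-%m-%d %H:%M:%S", tz = "UTC")
        write.csv(all_proj, proj_path, row.names = FALSE)
      }
      report_path <- file.path(config$out_dir, "report.json")
      jsonlite::write_json(unclass(report), report_path, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, null = "null")
      report$paths <- list(report = report_path, heat_index = hi_path,
                           projections = proj_path)
    })
  }

  report$fits <- lapply(models, `[[`, "fit")
  report$projections <- projections
  invisible(report)
}

#' @export
print.heatrisk_report <- function(x, ...) {
  cat("heatrisk pipeline report (seed ", x$seed, ")\n", sep = "")
  cat("  records:", x$qc$n_records, "\n")
  for (m in names(x$models)) {
    tm <- x$models[[m]]$test_metrics
    cat(sprintf("  %-8s test RMSE %.4f  MASE %.4f  R2 %.4f\n",
                m, tm$rmse, tm$mase, tm$r2))
  }
  if (!is.null(x$scenarios))
    for (s in names(x$scenarios))
      cat(sprintf("  scenario %-12s mean HI %.2f degC\n", s,
                  x$scenarios[[s]]$mean_hi))
  invisible(x)
}
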