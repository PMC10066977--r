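#' Run configuration
#'
#' All knobs of the end-to-end pipeline in one serializable list: sampling
#' ranges, physical constants, forward-model controls, MLP settings, dataset
#' sizes and seeds.
#'
#' @param ranges see [scenario_ranges()].
#' @param constants see [gas_constants()].
#' @param control see [forward_control()].
#' @param mlp see [mlp_config()].
#' @param n_scenarios retained scenario count.
#' @param n_test test-set size.
#' @param sat_band SaO2 retention band.
#' @param seed master seed; the dataset, split and MLP seeds are derived from
#'   it.
#' @return An object of class `run_config`.
#' @export
default_config <- function(ranges = scenario_ranges(),
                           constants = gas_constants(),
                           control = forward_control(),
                           mlp = mlp_config(),
                           n_scenarios = 15236, n_test = 500,
                           sat_band = c(0.87, 0.98), seed = 1L) {
  structure(list(ranges = ranges, constants = as.list(constants),
                 control = control, mlp = unclass(mlp),
                 n_scenarios = as.integer(n_scenarios),
                 n_test = as.integer(n_test), sat_band = sat_band,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' Round-trips losslessly through YAML.
#'
#' @param config a `run_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(cfg)) if (!is.null(x[[nm]])) cfg[[nm]] <- x[[nm]]
  cfg$ranges <- lapply(cfg$ranges, as.numeric)
  cfg$sat_band <- as.numeric(cfg$sat_band)
  cfg$mlp <- do.call(mlp_config, cfg$mlp)
  cfg$control <- do.call(forward_control, cfg$control)
  cfg$n_scenarios <- as.integer(cfg$n_scenarios)
  cfg$n_test <- as.integer(cfg$n_test)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

config_constants <- function(config) do.call(gas_constants, config$constants)

config_digest <- function(config) {
  f <- tempfile(fileext = ".yml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(config), f)
  unname(tools::md5sum(f))
}

validate_config <- function(config) {
  ok <- vapply(config$ranges, function(r) length(r) == 2 && r[1] < r[2], logical(1))
  if (!all(ok))
    stop("invalid ranges in config: ", paste(names(ok)[!ok], collapse = ", "))
  if (config$n_test >= config$n_scenarios)
    stop("n_test must be smaller than n_scenarios")
  invisible(config)
}

#' Generate and write the scenario dataset
#'
#' Samples the configured number of scenarios, titrates FiO2, runs the
#' forward model, randomizes the train/test split, and writes the dataset as
#' CSV (with a commented metadata header carrying the seed and config
#' digest).
#'
#' @param config a `run_config`.
#' @param path output CSV path.
#' @param quiet suppress progress messages.
#' @return The `scenario_dataset`, invisibly.
#' @export
cmd_simulate <- function(config = default_config(), path = "dataset.csv",
                         quiet = FALSE) {
  validate_config(config)
  ds <- build_dataset(config$n_scenarios, seed = config$seed,
                      sat_band = config$sat_band, ranges = config$ranges,
                      constants = config_constants(config),
                      control = config$control, quiet = quiet)
  ds <- randomize_split(ds, n_test = config$n_test, seed = config$seed + 1L)
  header <- sprintf("# vqshunt dataset; seed=%d; config_digest=%s",
                    config$seed, config_digest(config))
  con <- file(path, "w")
  writeLines(header, con)
  close(con)
  suppressWarnings(write.table(ds$records, path, append = TRUE, sep = ",",
                               row.names = FALSE, qmethod = "double"))
  invisible(ds)
}

#' Train the MLP and evaluate blinded recovery on the test split
#'
#' Trains the configured MLP on the training rows, predicts shunt blinded on
#' the test rows, and reports the actual-on-estimate regression and error
#' summary.
#'
#' @param config a `run_config`.
#' @param dataset a `scenario_dataset` or path to a dataset CSV written by
#'   [cmd_simulate()].
#' @param out_dir if non-NULL, reports are written there as JSON/CSV.
#' @return List with `model`, `regression`, `errors`, and the test-set
#'   `predictions`.
#' @export
cmd_train_eval <- function(config = default_config(), dataset,
                           out_dir = NULL) {
  if (is.character(dataset))
    dataset <- read_dataset(dataset, seed = config$seed)
  rec <- dataset$records
  if (is.null(rec$split)) stop("dataset has no split column; run cmd_simulate first")
  cfg <- config$mlp
  if (!inherits(cfg, "mlp_config")) cfg <- do.call(mlp_config, cfg)
  cfg$seed <- config$seed + 2L
  model <- train_shunt_mlp(dataset, cfg)
  test <- rec[rec$split == "test", ]
  est <- predict(model, test)
  reg <- regress_actual_on_estimate(test$shunt, est)
  err <- error_summary(test$shunt, est)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(config_digest = config_digest(config),
           regression = list(slope = reg$slope, intercept = reg$intercept,
                             r_squared = reg$r_squared, ci = reg$ci,
                             p_value = reg$p_value, n = reg$n),
           errors = list(mean = err$mean, sd = err$sd, median = err$median,
                         iqr = err$iqr, range = err$range,
                         skewness = err$skewness, shapiro_p = err$shapiro_p)),
      file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
    write.csv(kde_overlay(test$shunt, est),
              file.path(out_dir, "kde_overlay.csv"), row.names = FALSE)
    write.csv(data.frame(shunt = test$shunt, shunt_est = est),
              file.path(out_dir, "test_predictions.csv"), row.names = FALSE)
  }
  list(model = model, regression = reg, errors = err,
       predictions = data.frame(shunt = test$shunt, shunt_est = est))
}

#' Back-calculate one record (optionally with sensitivity sweeps)
#'
#' @param record a [bedside_record()], named list, or path to a one-row CSV /
#'   JSON file with the ten features.
#' @param sweep `NULL`, a vector of input names, or `"all"` for the nine
#'   non-FiO2 inputs.
#' @param out_dir if non-NULL, the report (JSON) and sweep curves (CSV, one
#'   per input) are written there.
#' @param sweep_args list of grid arguments for [sensitivity_sweep()]
#'   (`grid`, `n`, `rel`, `abs_pco2`).
#' @param ... passed to [recover_shunt()].
#' @return List with `report` and (if requested) `sweeps`.
#' @export
cmd_backcalc <- function(record, sweep = NULL, out_dir = NULL,
                         sweep_args = list(), ...) {
  if (is.character(record) && length(record) == 1 && file.exists(record)) {
    record <- if (grepl("\\.json$", record, ignore.case = TRUE))
      jsonlite::read_json(record, simplifyVector = TRUE)
    else read.csv(record)[1, ]
  }
  record <- as_bedside_record(record)
  report <- recover_shunt(record, ...)
  sweeps <- NULL
  if (!is.null(sweep)) {
    names_ <- if (identical(sweep, "all")) setdiff(ten_features, "fio2") else sweep
    sweeps <- lapply(names_, function(nm)
      do.call(sensitivity_sweep, c(list(record, nm), sweep_args, list(...))))
    names(sweeps) <- names_
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(shunt_est = report$shunt_est, venad_est = report$venad_est,
           low_vq_est = report$low_vq_est, log_sd = report$log_sd,
           mean_vq = report$mean_vq, converged = report$converged,
           residuals = as.list(report$residuals)),
      file.path(out_dir, "recovery_report.json"), auto_unbox = TRUE, digits = NA)
    for (nm in names(sweeps))
      write.csv(sweeps[[nm]]$curve,
                file.path(out_dir, paste0("sensitivity_", nm, ".csv")),
                row.names = FALSE)
  }
  list(report = report, sweeps = sweeps)
}
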