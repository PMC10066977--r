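#' Sampling ranges for the scenario generator
#'
#' The envelope of physiological model inputs used to build the simulation
#' universe: shunt (% of pulmonary blood flow), log-scale SD and mean of the
#' V/Q perfusion distribution, CO2 production, respiratory exchange ratio,
#' hemoglobin, standard P50, base excess and cardiac output.
#'
#' @return Named list of `c(low, high)` ranges.
#' @export
scenario_ranges <- function() {
  list(shunt   = c(7.3, 36.5),    # % of pulmonary blood flow
       log_sd  = c(0.36, 1.83),
       mean_vq = c(0.21, 1.25),
       vco2    = c(185, 223),     # mL/min
       r       = c(0.57, 1.05),
       hb      = c(6.0, 17.3),    # g/dL
       p50st   = c(20.8, 31.2),   # mmHg
       be      = c(-6.5, 4.9),    # mEq/L
       co      = c(4.32, 6.28))   # L/min
}

ten_features <- c("fio2", "hb", "sao2", "ph", "pao2", "paco2",
                  "mean_paco2", "co", "vco2", "r")

#' Sample model-input combinations
#'
#' Draws `n` unique input tuples, each variable independently uniform within
#' its range.  Reproducible by seed.
#'
#' @param n number of tuples.
#' @param ranges named list of ranges as in [scenario_ranges()].
#' @param seed integer seed.
#' @return Data frame with one row per tuple and the nine input columns.
#' @export
#' @examples
#' head(sample_inputs(5, seed = 1))
sample_inputs <- function(n, ranges = scenario_ranges(), seed = 1L) {
  stopifnot(n >= 1, all(vapply(ranges, function(r) r[1] < r[2], logical(1))))
  set.seed(seed)
  out <- as.data.frame(lapply(ranges, function(r) runif(n, r[1], r[2])))
  rownames(out) <- NULL
  out
}

inputs_from_row <- function(row) {
  lung_inputs(shunt = row$shunt / 100, log_sd = row$log_sd,
              mean_vq = row$mean_vq,
              metab = metabolic_state(vco2 = row$vco2, r = row$r, co = row$co),
              blood = blood_params(hb = row$hb, p50st = row$p50st, be = row$be))
}

record_from_result <- function(res, row) {
  data.frame(fio2 = res$fio2, hb = row$hb, sao2 = res$sao2, ph = res$ph,
             pao2 = res$pao2, paco2 = res$paco2, mean_paco2 = res$mean_paco2,
             co = row$co, vco2 = row$vco2, r = row$r,
             shunt = row$shunt, venad = 100 * res$venad,
             low_vq = 100 * res$venad - row$shunt,
             log_sd = row$log_sd, mean_vq = row$mean_vq,
             p50st = row$p50st, be = row$be)
}

#' Build the bedside-record dataset
#'
#' For each sampled input tuple, titrates FiO2 to the saturation band, runs
#' the forward model, and retains converged in-band records together with
#' their hidden truth labels (shunt, venous admixture, low V/Q, distribution
#' parameters).  Rejected scenarios (band unattainable or infeasible venous
#' state) are logged and, when `resample = TRUE`, replaced by fresh draws so
#' the requested count is reached.  The saturation aimed at within the band
#' is drawn uniformly per scenario, emulating the spread of titration
#' endpoints seen clinically.
#'
#' @param inputs data frame from [sample_inputs()], or an integer count to
#'   sample internally.
#' @param seed integer seed (drives per-scenario saturation targets and any
#'   resampling).
#' @param sat_band SaO2 retention band.
#' @param ranges ranges used when resampling.
#' @param resample replace rejected scenarios by fresh draws.
#' @param constants,control see [gas_constants()], [forward_control()].
#' @param quiet suppress the progress message.
#' @return An object of class `scenario_dataset`: list with `records` (data
#'   frame; ten feature columns in fixed order, then labels), `rejections`
#'   (reason counts), and `seed`.
#' @export
build_dataset <- function(inputs, seed = 1L, sat_band = c(0.87, 0.98),
                          ranges = scenario_ranges(), resample = TRUE,
                          constants = gas_constants(),
                          control = forward_control(), quiet = FALSE) {
  if (is.numeric(inputs) && length(inputs) == 1) {
    inputs <- sample_inputs(as.integer(inputs), ranges, seed = seed)
  }
  n_want <- nrow(inputs)
  set.seed(seed + 1L)
  targets <- runif(n_want, sat_band[1], sat_band[2])

  rows <- vector("list", n_want)
  reject <- character(0)
  kept <- 0L
  i <- 0L
  pending <- inputs
  while (kept < n_want) {
    i <- i + 1L
    if (i > nrow(pending)) {
      if (!resample) break
      extra <- sample_inputs(max(64L, n_want - kept),
                             ranges, seed = seed + 1000L + i)
      pending <- rbind(pending, extra)
      targets <- c(targets, runif(nrow(extra), sat_band[1], sat_band[2]))
    }
    row <- pending[i, , drop = FALSE]
    tt <- tryCatch(
      titrate_fio2(inputs_from_row(row), sat_band = sat_band,
                   target = targets[i], constants = constants,
                   control = control),
      error = function(e) list(feasible = FALSE, reason = conditionMessage(e)))
    if (isTRUE(tt$feasible)) {
      kept <- kept + 1L
      rows[[kept]] <- record_from_result(tt$result, row)
    } else {
      reject <- c(reject, tt$reason)
    }
    if (!resample && i >= nrow(inputs)) break
  }
  records <- do.call(rbind, rows[seq_len(kept)])
  rownames(records) <- NULL
  if (!quiet)
    message(sprintf("retained %d records (%d rejected)", kept, length(reject)))
  structure(list(records = records,
                 rejections = if (length(reject)) table(reject) else table(character(0)),
                 seed = seed, sat_band = sat_band),
            class = "scenario_dataset")
}

#' @export
print.scenario_dataset <- function(x, ...) {
  n <- nrow(x$records)
  cat(sprintf("Scenario dataset: %d records (seed %d)\n", n, x$seed))
  if (!is.null(x$records$split))
    cat(sprintf("  split: %d train / %d test\n",
                sum(x$records$split == "train"), sum(x$records$split == "test")))
  cat(sprintf("  rejected during generation: %d\n", sum(x$rejections)))
  invisible(x)
}

#' Randomize and split a dataset into train and test
#'
#' Simple randomization: rows are shuffled and `n_test` of them labelled
#' `test`, the remainder `train`.
#'
#' @param ds a `scenario_dataset`.
#' @param n_test number of test rows.
#' @param seed integer seed.
#' @return The dataset with a `split` column added to `records`.
#' @export
randomize_split <- function(ds, n_test = 500, seed = 1L) {
  stopifnot(inherits(ds, "scenario_dataset"))
  n <- nrow(ds$records)
  if (n_test >= n) stop("n_test must be smaller than the dataset size")
  set.seed(seed)
  ord <- sample.int(n)
  ds$records <- ds$records[ord, , drop = FALSE]
  rownames(ds$records) <- NULL
  ds$records$split <- rep("train", n)
  ds$records$split[seq_len(n_test)] <- "test"
  ds
}

#' Write / read a scenario dataset as CSV
#'
#' Column schema: the ten features `fio2, hb, sao2, ph, pao2, paco2,
#' mean_paco2, co, vco2, r`, then labels `shunt, venad, low_vq, log_sd,
#' mean_vq, p50st, be` and (if present) `split` and `shunt_est`.
#'
#' @param ds a `scenario_dataset`.
#' @param path file path.
#' @return `write_dataset` invisibly returns `path`; `read_dataset` returns a
#'   `scenario_dataset`.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "scenario_dataset"))
  write.csv(ds$records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @param seed seed recorded in the reconstructed object.
#' @export
read_dataset <- function(path, seed = NA_integer_) {
  rec <- read.csv(path, comment.char = "#")
  missing <- setdiff(ten_features, names(rec))
  if (length(missing))
    stop("dataset is missing feature columns: ", paste(missing, collapse = ", "))
  structure(list(records = rec, rejections = table(character(0)), seed = seed,
                 sat_band = c(min(rec$sao2), max(rec$sao2))),
            class = "scenario_dataset")
}
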