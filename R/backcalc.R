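#' A ten-feature bedside record
#'
#' The ten observable inputs of the single-FiO2 method: inspired oxygen
#' fraction, hemoglobin, arterial saturation, pH and gas tensions, mean
#' alveolar PCO2 (volumetric capnography), cardiac output, CO2 production and
#' respiratory exchange ratio.
#'
#' @param fio2 inspired O2 fraction.
#' @param hb hemoglobin (g/dL).
#' @param sao2 arterial O2 saturation fraction.
#' @param ph arterial pH.
#' @param pao2 arterial O2 tension (mmHg).
#' @param paco2 arterial CO2 tension (mmHg).
#' @param mean_paco2 mean alveolar PCO2 (mmHg).
#' @param co cardiac output (L/min).
#' @param vco2 CO2 production (mL/min).
#' @param r respiratory exchange ratio.
#' @return One-row data frame of class `bedside_record`.
#' @export
bedside_record <- function(fio2, hb, sao2, ph, pao2, paco2, mean_paco2,
                           co, vco2, r) {
  args <- list(fio2 = fio2, hb = hb, sao2 = sao2, ph = ph, pao2 = pao2,
               paco2 = paco2, mean_paco2 = mean_paco2, co = co,
               vco2 = vco2, r = r)
  bad <- names(args)[!vapply(args, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))]
  if (length(bad))
    stop("missing or non-numeric feature(s): ", paste(bad, collapse = ", "))
  structure(as.data.frame(args), class = c("bedside_record", "data.frame"))
}

as_bedside_record <- function(x) {
  if (inherits(x, "bedside_record")) return(x)
  x <- as.list(x)
  missing <- setdiff(ten_features, names(x))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  do.call(bedside_record, x[ten_features])
}

#' Reference gas-exchange scenario
#'
#' A representative bedside record in which both true shunt and low-V/Q
#' perfusion contribute to a substantial oxygenation deficit, used as the
#' anchor point for the sensitivity sweeps.
#'
#' @return A [bedside_record()].
#' @export
reference_record <- function() {
  bedside_record(fio2 = 0.38, hb = 9.30, sao2 = 0.94, ph = 7.364,
                 pao2 = 69.0, paco2 = 39.4, mean_paco2 = 30.1,
                 co = 5.25, vco2 = 187, r = 0.74)
}

#' Blood parameters implied by a bedside record
#'
#' Base excess is recovered from (pH, PaCO2, Hb) through the Van Slyke
#' relation, and the standard P50 from the measured (PaO2, SaO2) pair after
#' removing the in-vivo Bohr shifts, so that the dissociation curve passes
#' through the observed arterial point.
#'
#' @param record a [bedside_record()].
#' @param constants see [gas_constants()].
#' @return A [blood_params()] object.
#' @export
derived_blood_params <- function(record, constants = gas_constants()) {
  record <- as_bedside_record(record)
  be <- base_excess(record$ph, record$paco2, record$hb, constants)
  # standard-curve virtual PO2 at the observed saturation
  x <- cpp_odc_po2(record$sao2, 7.40, 40, 26.86, constants)
  p50iv <- record$pao2 * 26.86 / x
  shift <- 10^(-0.48 * (record$ph - 7.40) + 0.06 * log10(record$paco2 / 40))
  p50st <- p50iv / shift
  blood_params(hb = record$hb, p50st = min(max(p50st, 15), 40), be = max(min(be, 30), -30))
}

#' Venous admixture from a bedside record
#'
#' The Riley construction applied directly to the record: arterial O2 content
#' from (Hb, SaO2, PaO2); mixed venous content by Fick with `VO2 = VCO2 / R`;
#' ideal end-capillary content at the ideal alveolar PO2 for the operating
#' FiO2, arterial PCO2 and R.
#'
#' @inheritParams derived_blood_params
#' @return List with `venad` (fraction), the three O2 contents, and the ideal
#'   alveolar PO2.
#' @export
#' @examples
#' record_venad(reference_record())$venad
record_venad <- function(record, constants = gas_constants()) {
  record <- as_bedside_record(record)
  blood <- derived_blood_params(record, constants)
  ca <- o2_content(record$pao2, record$sao2, record$hb, constants)
  vo2 <- record$vco2 / record$r
  cv <- ca - vo2 / (10 * record$co)
  if (cv <= 0) stop("infeasible record: venous O2 content would be non-positive")
  pao2_id <- ideal_alveolar_po2(record$fio2, record$paco2, record$r, constants)
  ph_id <- acid_base_ph(record$paco2, blood$be, blood$hb, constants)
  s_id <- odc_saturation(pao2_id, ph_id, record$paco2, blood$p50st, constants)
  cc <- o2_content(pao2_id, s_id, record$hb, constants)
  list(venad = venous_admixture(cc, ca, cv),
       cc_o2 = cc, ca_o2 = ca, cv_o2 = cv, pao2_ideal = pao2_id)
}

feature_envelope <- function() {
  list(fio2 = c(0.21, 0.99), hb = c(4, 22), sao2 = c(0.5, 1), ph = c(6.8, 7.8),
       pao2 = c(25, 500), paco2 = c(10, 150), mean_paco2 = c(5, 120),
       co = c(2, 12), vco2 = c(80, 400), r = c(0.4, 1.3))
}

#' Direct model back-calculation of shunt from one bedside record
#'
#' The non-ML inverter: finds the lung-model parameters (shunt fraction,
#' log SD, mean V/Q) whose forward simulation at the record's FiO2,
#' metabolic and blood parameters reproduces the observed SaO2, PaCO2 and
#' mean alveolar PCO2.  PaO2 and pH are consistency inputs: they fix the
#' derived base excess and standard P50 (see [derived_blood_params()]) but
#' are not matched residuals.  Venous admixture is computed independently
#' from the record contents ([record_venad()]), and low V/Q is reported as
#' venous admixture minus shunt.
#'
#' @param record a [bedside_record()] (or coercible named list/row).
#' @param starts number of multistart initial points (first converged root is
#'   accepted).
#' @param residual_tol max absolute residual (percent saturation / mmHg) for
#'   a solution to count as converged.
#' @param warn_envelope warn when features fall outside the physiologic
#'   envelope.
#' @param constants,control see [gas_constants()], [forward_control()].
#' @return An object of class `recovery_report`: `shunt_est`, `venad_est`,
#'   `low_vq_est` (all % of pulmonary blood flow), fitted `log_sd` and
#'   `mean_vq`, residuals on the matched observables, and a convergence flag.
#' @export
#' @examples
#' \donttest{
#' recover_shunt(reference_record())
#' }
recover_shunt <- function(record, starts = 5, residual_tol = 0.05,
                          warn_envelope = TRUE,
                          constants = gas_constants(),
                          control = forward_control()) {
  record <- as_bedside_record(record)
  if (warn_envelope) {
    env <- feature_envelope()
    for (nm in names(env)) {
      v <- record[[nm]]
      if (v < env[[nm]][1] || v > env[[nm]][2])
        warning(sprintf("feature '%s' = %g is outside the physiologic envelope [%g, %g]",
                        nm, v, env[[nm]][1], env[[nm]][2]))
    }
  }
  blood <- derived_blood_params(record, constants)
  va <- record_venad(record, constants)
  venad_pct <- 100 * va$venad

  obs <- c(100 * record$sao2, record$paco2, record$mean_paco2)
  resid_fn <- function(par) {
    res <- tryCatch(
      cpp_run_forward(par[1], par[2], par[3], record$vco2, record$r,
                      blood$hb, blood$p50st, blood$be, record$co,
                      record$fio2, constants, control),
      error = function(e) NULL)
    if (is.null(res)) return(rep(1e3, 3))
    if (!isTRUE(res$feasible)) {
      # venous-infeasible states occur at excessive shunt: slope the penalty
      # so the solver is pushed back toward lower shunt
      return(rep(100 * (1 + par[1]), 3))
    }
    if (!isTRUE(res$converged)) return(rep(1e3, 3))
    c(100 * res$sao2, res$paco2, res$mean_paco2) - obs
  }

  lower <- c(1e-4, 0.05, 0.05)
  upper <- c(0.49, 2.6, 3.5)
  s0 <- min(max(va$venad, 0.02), 0.45)
  # total alveolar ventilation is pinned by mean PACO2 and VCO2; with a shunt
  # guess it implies the mean V/Q start
  va_total <- 0.863 * record$vco2 / record$mean_paco2 / record$co
  mv0 <- function(s) min(max(va_total / (1 - s), lower[3]), upper[3])
  s_grid <- pmin(pmax(c(0.60, 0.85, 0.35, 1.00, 0.70) * s0, lower[1]), 0.45)
  sd_grid <- c(1.00, 0.60, 1.50, 0.90, 1.20)
  start_list <- lapply(seq_along(s_grid), function(i)
    c(s_grid[i], sd_grid[i], mv0(s_grid[i])))
  start_list <- start_list[seq_len(min(starts, length(start_list)))]

  best <- NULL
  n_tried <- 0L
  run_lm <- function(st) {
    tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(st, lower), upper), fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 120, ftol = 1e-12, ptol = 1e-10)),
      error = function(e) NULL)
  }
  for (st in start_list) {
    n_tried <- n_tried + 1L
    fit <- run_lm(st)
    if (is.null(fit)) next
    r <- resid_fn(fit$par)
    cand <- list(par = fit$par, resid = r, maxres = max(abs(r)))
    if (is.null(best) || cand$maxres < best$maxres) best <- cand
    if (cand$maxres < residual_tol) break
  }
  if (!is.null(best) && best$maxres >= residual_tol) {
    # polish: derivative-free descent from the best point, then refit
    ss <- function(p) sum(resid_fn(p)^2)
    nm <- tryCatch(stats::optim(best$par, ss, method = "Nelder-Mead",
                                control = list(maxit = 300, reltol = 1e-12)),
                   error = function(e) NULL)
    if (!is.null(nm)) {
      fit <- run_lm(pmin(pmax(nm$par, lower), upper))
      if (!is.null(fit)) {
        r <- resid_fn(fit$par)
        if (max(abs(r)) < best$maxres)
          best <- list(par = fit$par, resid = r, maxres = max(abs(r)))
      }
    }
  }
  if (is.null(best))
    stop("back-calculation failed: no solver run completed")

  converged <- best$maxres < residual_tol
  shunt_pct <- 100 * best$par[1]
  structure(list(shunt_est = shunt_pct, venad_est = venad_pct,
                 low_vq_est = venad_pct - shunt_pct,
                 log_sd = best$par[2], mean_vq = best$par[3],
                 residuals = setNames(best$resid,
                                      c("sao2_pct", "paco2", "mean_paco2")),
                 converged = converged, starts_used = n_tried,
                 blood = blood, record = record),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Single-FiO2 back-calculation\n")
  cat(sprintf("  shunt %.1f%%   VenAd %.1f%%   low V/Q %.1f%%\n",
              x$shunt_est, x$venad_est, x$low_vq_est))
  cat(sprintf("  fitted log SD %.3f, mean V/Q %.3f;  converged: %s (max residual %.3g)\n",
              x$log_sd, x$mean_vq, x$converged, max(abs(x$residuals))))
  invisible(x)
}

#' Sensitivity of the back-calculated shunt to one monitoring input
#'
#' Re-runs [recover_shunt()] with one of the nine non-FiO2 inputs perturbed
#' above and below its recorded value, holding the others fixed, and reports
#' the estimated shunt and venous admixture along the grid together with the
#' central finite-difference slope at the unperturbed point.
#'
#' @param record a [bedside_record()].
#' @param input_name one of `hb, sao2, ph, pao2, paco2, mean_paco2, co,
#'   vco2, r`.
#' @param grid explicit grid of input values (must contain the unperturbed
#'   value), or `NULL` to use the default: +/- `rel` relative in `n` steps
#'   (+/- `abs_pco2` mmHg absolute for `paco2` and `mean_paco2`).
#' @param n grid size (odd, so the center point is included).
#' @param rel relative half-width of the default grid.
#' @param abs_pco2 absolute half-width (mmHg) for the two PCO2 inputs.
#' @param ... passed to [recover_shunt()].
#' @return An object of class `sensitivity_result`: data frame `curve`
#'   (`input_value`, `shunt_est`, `venad_est`, `converged`), the input name,
#'   and slopes (percentage points per input unit).
#' @export
sensitivity_sweep <- function(record, input_name, grid = NULL, n = 9,
                              rel = 0.10, abs_pco2 = 2, ...) {
  record <- as_bedside_record(record)
  varying <- setdiff(ten_features, "fio2")
  if (!input_name %in% varying)
    stop("input_name must be one of: ", paste(varying, collapse = ", "))
  v0 <- record[[input_name]]
  if (is.null(grid)) {
    half <- if (input_name %in% c("paco2", "mean_paco2")) abs_pco2 else rel * v0
    if (n %% 2 == 0) n <- n + 1
    grid <- v0 + seq(-half, half, length.out = n)
  }
  if (!any(abs(grid - v0) < 1e-12))
    grid <- sort(c(grid, v0))
  shunt_est <- venad_est <- rep(NA_real_, length(grid))
  conv <- logical(length(grid))
  for (i in seq_along(grid)) {
    rec_i <- record
    rec_i[[input_name]] <- grid[i]
    rep_i <- tryCatch(suppressWarnings(recover_shunt(rec_i, ...)),
                      error = function(e) NULL)
    if (!is.null(rep_i)) {
      shunt_est[i] <- rep_i$shunt_est
      venad_est[i] <- rep_i$venad_est
      conv[i] <- rep_i$converged
    }
  }
  k <- which.min(abs(grid - v0))
  slope <- function(y) {
    if (k > 1 && k < length(grid) && !is.na(y[k - 1]) && !is.na(y[k + 1]))
      (y[k + 1] - y[k - 1]) / (grid[k + 1] - grid[k - 1])
    else NA_real_
  }
  structure(list(input = input_name,
                 curve = data.frame(input_value = grid, shunt_est = shunt_est,
                                    venad_est = venad_est, converged = conv),
                 center_value = v0, center_index = k,
                 shunt_slope = slope(shunt_est),
                 venad_slope = slope(venad_est)),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Sensitivity of recovered shunt to '%s' (center %.4g)\n",
              x$input, x$center_value))
  cat(sprintf("  shunt slope %.3g pp per unit, VenAd slope %.3g pp per unit\n",
              x$shunt_slope, x$venad_slope))
  print(x$curve, row.names = FALSE)
  invisible(x)
}
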