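#' Lung model inputs
#'
#' The physiological inputs driving one forward simulation: true shunt
#' fraction, the dispersion and mean of the log-normal perfusion distribution
#' over V/Q, metabolic rates and blood properties.
#'
#' @param shunt fraction of pulmonary blood flow through V/Q = 0 regions,
#'   between 0 and 0.5.
#' @param log_sd dispersion (natural-log SD) of the log-normal perfusion
#'   distribution over V/Q, > 0.
#' @param mean_vq perfusion-weighted mean V/Q ratio of the ventilated
#'   compartments, > 0.
#' @param metab a [metabolic_state()] object.
#' @param blood a [blood_params()] object.
#' @return An object of class `lung_inputs`.
#' @export
#' @examples
#' lung_inputs(0.15, 1.0, 0.8, metabolic_state(200, 0.8, 5), blood_params(12))
lung_inputs <- function(shunt, log_sd, mean_vq, metab, blood) {
  stopifnot(shunt >= 0, shunt <= 0.5, log_sd > 0, mean_vq > 0,
            inherits(metab, "metabolic_state"), inherits(blood, "blood_params"))
  structure(list(shunt = shunt, log_sd = log_sd, mean_vq = mean_vq,
                 metab = metab, blood = blood), class = "lung_inputs")
}

#' Log-normal perfusion distribution over V/Q compartments
#'
#' Places `n` log-equally-spaced V/Q centers spanning
#' `mean_vq * exp(+/- max(span * log_sd, 1.2))` and assigns each compartment
#' the bin-integrated mass of the log-normal perfusion density whose
#' perfusion-weighted (arithmetic) mean V/Q is `mean_vq`, renormalized to sum
#' to one.  The grid half-width scales with the dispersion but never shrinks
#' below 1.2 log units, so nearly-degenerate distributions concentrate their
#' mass in single bins.  Ventilation fractions follow as `v_frac`
#' proportional to `q_frac * vq`.
#'
#' @param mean_vq perfusion-weighted mean V/Q, > 0.
#' @param log_sd log-scale SD, > 0.
#' @param n number of compartments.
#' @param span grid half-width in multiples of `log_sd`.
#' @return Data frame with columns `vq`, `q_frac`, `v_frac`.
#' @export
#' @examples
#' d <- perfusion_distribution(1.0, 0.5)
#' sum(d$q_frac)   # 1
perfusion_distribution <- function(mean_vq, log_sd, n = 20, span = 3.5) {
  stopifnot(mean_vq > 0, log_sd > 0, n >= 1)
  d <- cpp_perfusion_dist(mean_vq, log_sd, as.integer(n), span)
  v <- d$q_frac * d$vq
  data.frame(vq = d$vq, q_frac = d$q_frac, v_frac = v / sum(v))
}

#' Equilibrate a single V/Q compartment
#'
#' Solves the steady-state O2/CO2 mass balance of one compartment: gas-side
#' flux equals blood-side flux per unit perfusion, scaled by the V/Q ratio,
#' with nitrogen as the closure gas (alveolar partial pressures sum to
#' barometric minus water vapor pressure, and the inspired-to-expired
#' ventilation ratio is corrected for net gas exchange).  A compartment with
#' `vq = 0` returns mixed venous blood unchanged.
#'
#' @param vq ventilation/perfusion ratio, >= 0.
#' @param fio2 inspired oxygen fraction.
#' @param venous list with mixed venous contents `cvo2`, `cvco2` (mL/dL).
#' @param blood a [blood_params()] object.
#' @param constants see [gas_constants()].
#' @return List with alveolar tensions (`pao2`, `paco2`, `pan2`),
#'   end-capillary state (`po2`, `pco2`, `ph`, `so2`, `cc_o2`, `cc_co2`) and
#'   gas/blood flux diagnostics (mL/min per unit blood flow).
#' @export
equilibrate_compartment <- function(vq, fio2, venous, blood,
                                    constants = gas_constants()) {
  stopifnot(vq >= 0, fio2 > 0, fio2 <= 1)
  res <- cpp_equilibrate(vq, fio2, venous$cvo2, venous$cvco2,
                         blood$hb, blood$p50st, blood$be, constants)
  if (!res$converged)
    stop(sprintf(paste0("compartment solver did not converge (vq = %g): ",
                        "flux residuals O2 %.3g, CO2 %.3g"),
                 vq, res$o2_flux_gas - res$o2_flux_blood,
                 res$co2_flux_gas - res$co2_flux_blood))
  res
}

#' Run the forward lung model
#'
#' Distributes perfusion over 20 ventilated V/Q compartments plus a shunt
#' compartment, equilibrates each compartment, mixes arterial blood by
#' perfusion-weighted content averaging (shunt contributes mixed venous
#' blood), forms the ventilation-weighted mean alveolar PCO2, and closes the
#' mixed venous loop by the Fick principle via a damped fixed-point
#' iteration.
#'
#' @param inputs a [lung_inputs()] object.
#' @param fio2 inspired oxygen fraction between 0.21 and 1.
#' @param constants see [gas_constants()].
#' @param control see [forward_control()].
#' @return An object of class `forward_result`: a list with the arterial and
#'   mixed venous blood gas state, `mean_paco2`, venous admixture `venad`,
#'   `low_vq = venad - shunt`, conservation diagnostics, and a
#'   `compartments` matrix.
#' @export
#' @examples
#' inp <- lung_inputs(0.10, 0.8, 0.9, metabolic_state(200, 0.8, 5.5),
#'                    blood_params(12))
#' f <- run_forward(inp, fio2 = 0.30)
#' c(f$sao2, f$venad)
run_forward <- function(inputs, fio2, constants = gas_constants(),
                        control = forward_control()) {
  stopifnot(inherits(inputs, "lung_inputs"), fio2 >= 0.21, fio2 <= 1)
  res <- cpp_run_forward(inputs$shunt, inputs$log_sd, inputs$mean_vq,
                         inputs$metab$vco2, inputs$metab$r,
                         inputs$blood$hb, inputs$blood$p50st, inputs$blood$be,
                         inputs$metab$co, fio2, constants, control)
  if (!res$feasible)
    stop("infeasible scenario: mixed venous O2 content fell to zero")
  if (!res$converged)
    stop(sprintf("forward model did not converge in %d iterations (delta %.3g)",
                 res$iterations, res$delta))
  res$inputs <- inputs
  class(res) <- "forward_result"
  res
}

#' @export
print.forward_result <- function(x, ...) {
  cat("Forward V/Q lung model result\n")
  cat(sprintf("  FiO2 %.3f  SaO2 %.3f  PaO2 %.1f  PaCO2 %.1f  pH %.3f\n",
              x$fio2, x$sao2, x$pao2, x$paco2, x$ph))
  cat(sprintf("  mean PACO2 %.1f mmHg,  VenAd %.1f%%,  shunt %.1f%%,  low V/Q %.1f%%\n",
              x$mean_paco2, 100 * x$venad, 100 * x$inputs$shunt, 100 * x$low_vq))
  invisible(x)
}

#' Venous admixture from oxygen contents
#'
#' The Riley three-compartment construct: the virtual shunt fraction that,
#' mixing ideal end-capillary blood with mixed venous blood, reproduces the
#' observed arterial O2 content: `(CcO2 - CaO2) / (CcO2 - CvO2)`.
#'
#' @param cc_o2 end-capillary O2 content of the ideal compartment (mL/dL).
#' @param ca_o2 arterial O2 content (mL/dL).
#' @param cv_o2 mixed venous O2 content (mL/dL).
#' @return Venous admixture as a fraction of pulmonary blood flow.
#' @export
#' @examples
#' venous_admixture(20, 18, 14)   # 1/3
venous_admixture <- function(cc_o2, ca_o2, cv_o2) {
  if (any(cc_o2 <= cv_o2))
    stop("degenerate scenario: end-capillary content must exceed venous content")
  (cc_o2 - ca_o2) / (cc_o2 - cv_o2)
}

#' Ideal alveolar PO2
#'
#' Classic alveolar gas equation at the operating FiO2, with the arterial
#' PCO2 standing in for the ideal alveolar PCO2:
#' `PIO2 - PaCO2 * (FiO2 + (1 - FiO2) / R)`.
#'
#' @param fio2 inspired oxygen fraction.
#' @param paco2 arterial CO2 tension (mmHg).
#' @param r respiratory exchange ratio.
#' @param constants see [gas_constants()].
#' @return Ideal alveolar PO2 (mmHg).
#' @export
ideal_alveolar_po2 <- function(fio2, paco2, r, constants = gas_constants()) {
  pio2 <- fio2 * (constants[["pb"]] - constants[["ph2o"]])
  pio2 - paco2 * (fio2 + (1 - fio2) / r)
}

#' Titrate FiO2 to an arterial saturation band
#'
#' Finds an inspired oxygen fraction whose forward-model SaO2 lies within the
#' target band, by bisection on the monotone SaO2(FiO2) map.  The lower bound
#' 0.21 is returned when the scenario is already in band on room air.
#'
#' @param inputs a [lung_inputs()] object.
#' @param sat_band SaO2 acceptance band (default `c(0.87, 0.98)`).
#' @param target saturation aimed at inside the band (default the midpoint).
#' @param fio2_range admissible FiO2 range.
#' @param constants,control see [gas_constants()], [forward_control()].
#' @return List with `feasible`; when feasible, `fio2` and the
#'   `forward_result` at that FiO2; otherwise a `reason` string.
#' @export
titrate_fio2 <- function(inputs, sat_band = c(0.87, 0.98),
                         target = mean(sat_band), fio2_range = c(0.21, 0.99),
                         constants = gas_constants(),
                         control = forward_control()) {
  stopifnot(inherits(inputs, "lung_inputs"), length(sat_band) == 2,
            sat_band[1] < sat_band[2],
            target >= sat_band[1], target <= sat_band[2])
  res <- cpp_titrate(inputs$shunt, inputs$log_sd, inputs$mean_vq,
                     inputs$metab$vco2, inputs$metab$r,
                     inputs$blood$hb, inputs$blood$p50st, inputs$blood$be,
                     inputs$metab$co, sat_band[1], sat_band[2], target,
                     fio2_range[1], fio2_range[2], constants, control)
  if (isTRUE(res$feasible)) {
    r <- res$result
    r$inputs <- inputs
    class(r) <- "forward_result"
    list(feasible = TRUE, fio2 = res$fio2, result = r)
  } else {
    list(feasible = FALSE, reason = res$reason)
  }
}
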