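#' Physical and chemical constants of the gas-exchange model
#'
#' All constants used by the blood chemistry and lung model, overridable for
#' sensitivity work.  Defaults: Hufner constant 1.34 mL O2/g Hb, O2 solubility
#' 0.003 mL/dL/mmHg, CO2 solubility 0.0307 mmol/L/mmHg, barometric pressure
#' 760 mmHg, water vapor pressure 47 mmHg (37 C).
#'
#' @param hufner mL of O2 bound per gram of fully saturated hemoglobin.
#' @param alpha_o2 O2 solubility in blood (mL/dL/mmHg).
#' @param s_co2 CO2 solubility in plasma (mmol/L/mmHg).
#' @param pb barometric pressure (mmHg).
#' @param ph2o water vapor pressure at body temperature (mmHg).
#' @return Named numeric vector of constants.
#' @export
#' @examples
#' gas_constants()
#' gas_constants(hufner = 1.36)
gas_constants <- function(hufner = 1.34, alpha_o2 = 0.003, s_co2 = 0.0307,
                          pb = 760, ph2o = 47) {
  c(hufner = hufner, alpha_o2 = alpha_o2, s_co2 = s_co2, pb = pb, ph2o = ph2o)
}

#' Numerical controls for the forward lung model
#'
#' @param n_compartments number of ventilated V/Q compartments (the shunt
#'   compartment is additional).
#' @param grid_span half-width of the compartment grid in units of `log_sd`
#'   around the mean V/Q (log scale).
#' @param damping relaxation factor on the mixed-venous fixed-point update.
#' @param venous_tol convergence tolerance on mixed venous contents (mL/dL).
#' @param max_iter maximum venous fixed-point iterations.
#' @return List of controls.
#' @export
forward_control <- function(n_compartments = 20, grid_span = 3.5,
                            damping = 0.5, venous_tol = 1e-6, max_iter = 200) {
  stopifnot(n_compartments >= 1, grid_span > 0, damping > 0, damping <= 1,
            venous_tol > 0, max_iter >= 1)
  list(n_compartments = as.integer(n_compartments), grid_span = grid_span,
       damping = damping, venous_tol = venous_tol, max_iter = as.integer(max_iter))
}
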