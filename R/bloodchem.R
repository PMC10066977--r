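#' Blood composition parameters
#'
#' Hemoglobin concentration, standard P50 (hemoglobin-oxygen affinity) and
#' base excess, the three quantities that determine how a given blood sample
#' carries oxygen and carbon dioxide at 37 C.
#'
#' @param hb hemoglobin concentration (g/dL), > 0.
#' @param p50st standard P50 (mmHg): PO2 at 50% saturation at pH 7.40,
#'   PCO2 40 mmHg, 37 C.  Must lie between 15 and 40.
#' @param be base excess (mEq/L), between -30 and 30.
#' @return An object of class `blood_params`.
#' @export
#' @examples
#' blood_params(hb = 15, p50st = 26.86, be = 0)
blood_params <- function(hb, p50st = 26.86, be = 0) {
  stopifnot(is.numeric(hb), hb > 0,
            p50st >= 15, p50st <= 40,
            be >= -30, be <= 30)
  structure(list(hb = hb, p50st = p50st, be = be), class = "blood_params")
}

#' Metabolic state: gas exchange rates and cardiac output
#'
#' @param vco2 CO2 production (mL/min STPD), > 0.
#' @param r respiratory exchange ratio VCO2/VO2, > 0.
#' @param co cardiac output (L/min), > 0.
#' @return An object of class `metabolic_state` with the derived O2
#'   consumption `vo2 = vco2 / r`.
#' @export
#' @examples
#' metabolic_state(vco2 = 187, r = 0.74, co = 5.25)
metabolic_state <- function(vco2, r, co) {
  stopifnot(vco2 > 0, r > 0, co > 0)
  structure(list(vco2 = vco2, r = r, vo2 = vco2 / r, co = co),
            class = "metabolic_state")
}

#' Oxyhemoglobin saturation
#'
#' Saturation from PO2 on a Severinghaus-form dissociation curve whose in-vivo
#' P50 is the standard P50 scaled by multiplicative Bohr corrections for pH
#' and PCO2 (base excess acts through its effect on pH).
#'
#' @param po2 oxygen tension (mmHg), >= 0.
#' @param ph blood pH.
#' @param pco2 CO2 tension (mmHg).
#' @param p50st standard P50 (mmHg).
#' @param constants see [gas_constants()].
#' @return Saturation fraction between 0 and 1.
#' @export
#' @examples
#' odc_saturation(26.86, 7.40, 40)   # 0.5 by definition of standard P50
#' odc_saturation(100, 7.40, 40)
odc_saturation <- function(po2, ph = 7.40, pco2 = 40, p50st = 26.86,
                           constants = gas_constants()) {
  if (any(po2 < 0)) stop("po2 must be non-negative")
  vapply(seq_along(po2), function(i)
    cpp_odc_sat(po2[i], rep_len(ph, length(po2))[i],
                rep_len(pco2, length(po2))[i], p50st, constants),
    numeric(1))
}

#' Inverse dissociation curve: PO2 at a given saturation
#'
#' @param so2 saturation fraction in (0, 1).
#' @inheritParams odc_saturation
#' @return PO2 (mmHg).
#' @export
odc_po2 <- function(so2, ph = 7.40, pco2 = 40, p50st = 26.86,
                    constants = gas_constants()) {
  stopifnot(all(so2 >= 0), all(so2 < 1))
  vapply(so2, cpp_odc_po2, numeric(1), ph = ph, pco2 = pco2, p50st = p50st,
         consts = constants)
}

#' Blood oxygen content
#'
#' Hemoglobin-bound plus dissolved oxygen:
#' `hufner * hb * so2 + alpha_o2 * po2` (mL/dL).
#'
#' @param po2 oxygen tension (mmHg).
#' @param so2 saturation fraction between 0 and 1.
#' @param hb hemoglobin (g/dL).
#' @inheritParams odc_saturation
#' @return O2 content (mL/dL).
#' @export
#' @examples
#' o2_content(69, 0.94, hb = 9.3)
o2_content <- function(po2, so2, hb, constants = gas_constants()) {
  stopifnot(all(so2 >= 0), all(so2 <= 1))
  cpp_o2_content(po2, so2, hb, constants)
}

#' Blood carbon dioxide content
#'
#' Whole-blood CO2 content (dissolved + bicarbonate + saturation-dependent
#' carriage) in mL/dL, a Douglas-form equation.  Exhibits the Haldane effect:
#' at fixed PCO2, content rises as saturation falls.
#'
#' @param pco2 CO2 tension (mmHg), >= 0.
#' @param ph blood pH.
#' @param so2 hemoglobin O2 saturation fraction.
#' @param hb hemoglobin (g/dL).
#' @inheritParams odc_saturation
#' @return CO2 content (mL/dL).
#' @export
co2_content <- function(pco2, ph, so2, hb, constants = gas_constants()) {
  stopifnot(all(pco2 >= 0))
  cpp_co2_content(pco2, ph, so2, hb, constants)
}

#' pH from PCO2 and base excess (Van Slyke buffer relation)
#'
#' Solves the whole-blood Van Slyke relation for pH at a given PCO2, base
#' excess and hemoglobin.  Monotone decreasing in PCO2 and increasing in BE.
#'
#' @param pco2 CO2 tension (mmHg), > 0.
#' @param be base excess (mEq/L).
#' @param hb hemoglobin (g/dL).
#' @inheritParams odc_saturation
#' @return pH.
#' @export
#' @examples
#' acid_base_ph(40, be = 0)   # ~7.40
acid_base_ph <- function(pco2, be = 0, hb = 15, constants = gas_constants()) {
  if (any(pco2 <= 0)) stop("pco2 must be positive")
  vapply(pco2, cpp_ph_from, numeric(1), be = be, hb = hb, consts = constants)
}

#' Base excess from measured pH and PCO2
#'
#' The forward Van Slyke relation; the inverse of [acid_base_ph()].
#'
#' @param ph blood pH.
#' @param pco2 CO2 tension (mmHg).
#' @param hb hemoglobin (g/dL).
#' @inheritParams odc_saturation
#' @return Base excess (mEq/L).
#' @export
base_excess <- function(ph, pco2, hb = 15, constants = gas_constants()) {
  cpp_vanslyke_be(ph, pco2, hb, constants)
}

#' Full blood gas state from O2 and CO2 contents
#'
#' Inverts the content relations: given total O2 and CO2 contents, base excess
#' and hemoglobin properties, recovers (PO2, PCO2, pH, SO2).
#'
#' @param o2ct O2 content (mL/dL).
#' @param co2ct CO2 content (mL/dL).
#' @param blood a [blood_params()] object.
#' @inheritParams odc_saturation
#' @return List with `po2`, `pco2`, `ph`, `so2`.
#' @export
blood_from_contents <- function(o2ct, co2ct, blood, constants = gas_constants()) {
  cpp_blood_from_contents(o2ct, co2ct, blood$hb, blood$p50st, blood$be, constants)
}

#' Mixed venous blood state by the Fick principle
#'
#' Venous contents follow from arterial contents, metabolic rates and cardiac
#' output: `CvO2 = CaO2 - VO2 / (10 CO)` and `CvCO2 = CaCO2 + VCO2 / (10 CO)`
#' (the factor 10 converts mL/dL to mL/L).  Venous tensions, pH and
#' saturation are recovered by inverting the content relations.
#'
#' @param arterial list with at least `cao2` and `caco2` (mL/dL), e.g. a
#'   forward-model result.
#' @param metab a [metabolic_state()] object.
#' @param blood a [blood_params()] object.
#' @inheritParams odc_saturation
#' @return List with venous `cvo2`, `cvco2`, `po2`, `pco2`, `ph`, `so2`.
#' @export
#' @examples
#' bl <- blood_params(hb = 9.3)
#' mixed_venous(list(cao2 = 11.92, caco2 = 45), metabolic_state(187, 0.74, 5.25), bl)
mixed_venous <- function(arterial, metab, blood, constants = gas_constants()) {
  cvo2 <- arterial$cao2 - metab$vo2 / (10 * metab$co)
  cvco2 <- arterial$caco2 + metab$vco2 / (10 * metab$co)
  if (cvo2 <= 0)
    stop("infeasible scenario: mixed venous O2 content would be non-positive")
  g <- blood_from_contents(cvo2, cvco2, blood, constants)
  c(list(cvo2 = cvo2, cvco2 = cvco2), g)
}
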