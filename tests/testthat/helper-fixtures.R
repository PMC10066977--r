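# Shared fixtures, built in code.  The small dataset is generated once per
# test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

ref_inputs <- function(shunt = 0.12, log_sd = 0.9, mean_vq = 0.8,
                       vco2 = 200, r = 0.8, co = 5.5, hb = 12,
                       p50st = 26.86, be = 0) {
  lung_inputs(shunt, log_sd, mean_vq,
              metabolic_state(vco2 = vco2, r = r, co = co),
              blood_params(hb = hb, p50st = p50st, be = be))
}

small_dataset <- function() {
  if (is.null(.fixture_env$small_ds)) {
    ds <- build_dataset(250, seed = 42, quiet = TRUE)
    .fixture_env$small_ds <- randomize_split(ds, n_test = 50, seed = 43)
  }
  .fixture_env$small_ds
}

# independent Severinghaus-form oracle (standard conditions)
sev_oracle <- function(po2) {
  t <- po2^3 + 150 * po2
  t / (t + 23400)
}

# independent Douglas-form CO2 content oracle (mL/dL)
co2_oracle <- function(pco2, ph, so2, hb) {
  plasma <- 0.0307 * pco2 * (1 + 10^(ph - 6.105))
  fac <- 1 - 0.0289 * hb / ((3.352 - 0.456 * so2) * (8.142 - ph))
  plasma * fac * 2.226
}

# independent Van Slyke oracle: base excess from pH, PCO2, Hb
be_oracle <- function(ph, pco2, hb) {
  hco3 <- 0.0307 * pco2 * 10^(ph - 6.105)
  (1 - 0.0143 * hb) * ((hco3 - 24.4) + (2.3 * hb + 7.7) * (ph - 7.40))
}
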