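test_that("bedside records validate their ten features", {
  expect_error(bedside_record(fio2 = 0.3, hb = 12, sao2 = 0.93, ph = 7.4,
                              pao2 = 70, paco2 = 40, mean_paco2 = NA,
                              co = 5, vco2 = 200, r = 0.8), "mean_paco2")
  expect_error(vqshunt:::as_bedside_record(list(fio2 = 0.3, hb = 12)), "sao2")
})

test_that("blood parameters derived from a record reproduce its arterial point", {
  r <- reference_record()
  bl <- derived_blood_params(r)
  expect_equal(base_excess(r$ph, r$paco2, r$hb), bl$be, tolerance = 1e-9)
  # the derived curve passes through the measured (PaO2, SaO2) pair
  expect_equal(odc_saturation(r$pao2, r$ph, r$paco2, bl$p50st), r$sao2,
               tolerance = 1e-6)
})

test_that("record-based venous admixture follows the Riley construction", {
  r <- reference_record()
  va <- record_venad(r)
  expect_equal(va$ca_o2, 1.34 * 9.30 * 0.94 + 0.003 * 69.0, tolerance = 1e-9)
  expect_equal(va$cv_o2, va$ca_o2 - (187 / 0.74) / 52.5, tolerance = 1e-9)
  expect_equal(va$pao2_ideal,
               0.38 * 713 - 39.4 * (0.38 + 0.62 / 0.74), tolerance = 1e-9)
  expect_equal(va$venad,
               (va$cc_o2 - va$ca_o2) / (va$cc_o2 - va$cv_o2), tolerance = 1e-12)
  expect_gt(va$venad, 0.1)
  expect_lt(va$venad, 0.3)
})

test_that("back-calculation inverts forward-generated records", {
  set.seed(31)
  n_ok <- 0
  for (i in 1:6) {
    x <- sample_inputs(1, seed = 500 + i)
    inp <- vqshunt:::inputs_from_row(x)
    tt <- titrate_fio2(inp, target = runif(1, 0.88, 0.97))
    if (!tt$feasible) next
    rec <- vqshunt:::record_from_result(tt$result, x)
    rep <- suppressWarnings(recover_shunt(rec[, vqshunt:::ten_features]))
    expect_true(rep$converged)
    expect_lt(abs(rep$shunt_est - x$shunt), 0.3)
    expect_lt(abs(rep$log_sd - x$log_sd), 0.05)
    expect_lt(abs(rep$mean_vq - x$mean_vq), 0.05)
    n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 4)
})

test_that("a pure-shunt record yields negligible low V/Q", {
  inp <- ref_inputs(shunt = 0.15, log_sd = 0.05, mean_vq = 0.9)
  tt <- titrate_fio2(inp)
  rec <- vqshunt:::record_from_result(
    tt$result, data.frame(shunt = 15, log_sd = 0.05, mean_vq = 0.9,
                          vco2 = 200, r = 0.8, hb = 12, p50st = 26.86,
                          be = 0, co = 5.5))
  rep <- suppressWarnings(recover_shunt(rec[, vqshunt:::ten_features]))
  expect_lt(abs(rep$venad_est - rep$shunt_est), 1)
})

test_that("out-of-envelope features warn but do not fail", {
  r <- reference_record()
  r$hb <- 2  # far below any physiologic hemoglobin
  expect_warning(try(recover_shunt(r, starts = 1), silent = TRUE), "envelope")
})

test_that("sensitivity sweeps report curves and slopes around the center", {
  r <- reference_record()
  sw <- sensitivity_sweep(r, "mean_paco2", grid = c(29.1, 30.1, 31.1))
  expect_equal(nrow(sw$curve), 3)
  expect_equal(sw$curve$input_value[sw$center_index], 30.1)
  # raising mean PACO2 raises the shunt estimate, ~2 pp per mmHg
  expect_gt(sw$shunt_slope, 1)
  expect_lt(sw$shunt_slope, 3)
  # the center point agrees with the direct report
  rep <- suppressWarnings(recover_shunt(r))
  expect_equal(sw$curve$shunt_est[sw$center_index], rep$shunt_est,
               tolerance = 0.05)
  expect_error(sensitivity_sweep(r, "fio2"), "input_name")
})
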