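test_that("perfusion distribution matches quadrature of the log-normal", {
  d <- perfusion_distribution(1.0, 0.5)
  expect_equal(sum(d$q_frac), 1, tolerance = 1e-12)
  expect_equal(sum(d$v_frac), 1, tolerance = 1e-12)
  # quadrature oracle: bin-integrate the log-normal density whose
  # perfusion-weighted mean is mean_vq
  mu <- log(1.0) - 0.5 * 0.5^2
  lc <- seq(log(1.0) - 3.5 * 0.5, log(1.0) + 3.5 * 0.5, length.out = 20)
  h <- diff(lc)[1]
  w <- plnorm(exp(lc + h / 2), mu, 0.5) - plnorm(exp(lc - h / 2), mu, 0.5)
  w <- w / sum(w)
  expect_equal(d$q_frac, w, tolerance = 1e-6)
  expect_equal(d$vq, exp(lc), tolerance = 1e-12)
  # ventilation implied by perfusion and V/Q
  expect_equal(d$v_frac, d$q_frac * d$vq / sum(d$q_frac * d$vq), tolerance = 1e-12)
})

test_that("degenerate dispersion concentrates perfusion at the mean", {
  d <- perfusion_distribution(0.7, 0.001)
  nearest <- order(abs(log(d$vq / 0.7)))[1:2]
  expect_gt(sum(d$q_frac[nearest]), 0.999)
  expect_lt(max(abs(log(d$vq[nearest] / 0.7))), 0.1)
})

test_that("a shunt compartment returns venous blood unchanged", {
  bl <- blood_params(hb = 12)
  ven <- list(cvo2 = 11, cvco2 = 50)
  res <- equilibrate_compartment(0, 0.21, ven, bl)
  expect_equal(res$cc_o2, 11)
  expect_equal(res$cc_co2, 50)
})

test_that("an over-ventilated compartment approaches inspired gas", {
  bl <- blood_params(hb = 12)
  ven <- list(cvo2 = 11, cvco2 = 50)
  res <- equilibrate_compartment(1000, 0.21, ven, bl)
  expect_equal(res$pao2, 0.21 * 713, tolerance = 2)
  expect_lt(res$paco2, 1)
})

test_that("compartment fluxes balance between gas and blood sides", {
  bl <- blood_params(hb = 14, p50st = 27, be = -3)
  ven <- list(cvo2 = 10.5, cvco2 = 52)
  for (vq in c(0.05, 0.3, 1, 4, 20)) {
    res <- equilibrate_compartment(vq, 0.35, ven, bl)
    expect_lt(abs(res$o2_flux_gas - res$o2_flux_blood), 1e-6)
    expect_lt(abs(res$co2_flux_gas - res$co2_flux_blood), 1e-6)
    # N2 closure
    expect_equal(res$pao2 + res$paco2 + res$pan2, 713, tolerance = 1e-6)
  }
})

test_that("a homogeneous lung without shunt has negligible admixture", {
  inp <- ref_inputs(shunt = 0, log_sd = 0.01, mean_vq = 1.0)
  f <- run_forward(inp, fio2 = 0.21)
  expect_lt(f$venad, 0.01)
})

test_that("saturation falls strictly as shunt rises", {
  sats <- vapply(c(0.05, 0.15, 0.25, 0.35), function(s)
    run_forward(ref_inputs(shunt = s), fio2 = 0.4)$sao2, numeric(1))
  expect_true(all(diff(sats) < 0))
})

test_that("the converged forward model conserves whole-lung gas exchange", {
  for (fio2 in c(0.21, 0.5, 0.9)) {
    f <- run_forward(ref_inputs(), fio2 = fio2)
    vo2 <- 200 / 0.8
    expect_lt(abs(f$o2_uptake - vo2) / vo2, 1e-3)
    expect_lt(abs(f$co2_output - 200) / 200, 1e-3)
    # alveolar pressures close to barometric minus water vapor everywhere
    cm <- f$compartments
    expect_equal(unname(cm[, "pao2"] + cm[, "paco2"] + cm[, "pan2"]),
                 rep(713, nrow(cm)), tolerance = 1e-6)
  }
})

test_that("pure-shunt limit: admixture collapses onto shunt as log SD shrinks", {
  inp <- ref_inputs(shunt = 0.15, log_sd = 0.05, mean_vq = 0.9)
  f <- run_forward(inp, fio2 = 0.35)
  expect_lt(abs(100 * f$venad - 15), 0.5)
})

test_that("doubling the compartment count barely moves arterial PO2", {
  inp <- ref_inputs(shunt = 0.18, log_sd = 1.2, mean_vq = 0.6)
  f20 <- run_forward(inp, fio2 = 0.5)
  f40 <- run_forward(inp, fio2 = 0.5, control = forward_control(n_compartments = 40))
  expect_lt(abs(f20$pao2 - f40$pao2), 1)
})

test_that("venous admixture equation handles its edge cases", {
  expect_equal(venous_admixture(20, 20, 14), 0)
  expect_equal(venous_admixture(20, 14, 14), 1)
  expect_equal(venous_admixture(20, 18, 14), 1 / 3)
  expect_error(venous_admixture(10, 9, 12), "degenerate")
})

test_that("FiO2 titration lands in the saturation band", {
  # healthy enough to be in band on room air
  inp <- ref_inputs(shunt = 0.08, log_sd = 0.5, mean_vq = 1.0)
  tt <- titrate_fio2(inp)
  expect_true(tt$feasible)
  expect_equal(tt$fio2, 0.21)
  # sicker lung needs oxygen
  inp2 <- ref_inputs(shunt = 0.30, log_sd = 1.5, mean_vq = 0.4, hb = 8)
  tt2 <- titrate_fio2(inp2)
  expect_true(tt2$feasible)
  expect_gt(tt2$fio2, 0.21)
  expect_gte(tt2$result$sao2, 0.87)
  expect_lte(tt2$result$sao2, 0.98)
  # SaO2 is non-decreasing in FiO2 (skipping venous-infeasible low FiO2)
  sats <- vapply(c(0.21, 0.35, 0.5, 0.7, 0.9), function(f)
    tryCatch(run_forward(inp2, f)$sao2, error = function(e) NA_real_),
    numeric(1))
  expect_true(all(diff(sats[!is.na(sats)]) > -1e-9))
})
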