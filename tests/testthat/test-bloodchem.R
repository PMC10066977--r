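test_that("dissociation curve passes through the standard P50 and limits", {
  expect_equal(odc_saturation(26.86, 7.40, 40), 0.5, tolerance = 1e-3)
  expect_equal(odc_saturation(0, 7.40, 40), 0)
  # independent oracle at standard conditions
  for (po2 in c(20, 40, 60, 100, 150)) {
    expect_equal(odc_saturation(po2, 7.40, 40, p50st = 26.86),
                 sev_oracle(po2), tolerance = 1e-6)
  }
  expect_equal(odc_saturation(150, 7.40, 40), 0.9932, tolerance = 1e-3)
  expect_error(odc_saturation(-1, 7.40, 40), "non-negative")
})

test_that("dissociation curve is sigmoidal, monotone, and P50-shifted", {
  po2 <- seq(1, 300, by = 1)
  s <- odc_saturation(po2, 7.40, 40)
  expect_true(all(diff(s) > 0))
  expect_true(all(s >= 0 & s <= 1))
  # Bohr effect: acidosis and hypercapnia right-shift the curve
  expect_lt(odc_saturation(40, 7.20, 40), odc_saturation(40, 7.40, 40))
  expect_lt(odc_saturation(40, 7.40, 60), odc_saturation(40, 7.40, 40))
  # raising P50st at fixed PO2 strictly lowers saturation
  p50 <- seq(20.8, 31.2, length.out = 8)
  sat <- vapply(p50, function(p) odc_saturation(40, 7.40, 40, p50st = p), numeric(1))
  expect_true(all(diff(sat) < 0))
})

test_that("saturation/PO2 inversion round-trips", {
  for (po2 in c(15, 26.86, 55, 90, 200)) {
    s <- odc_saturation(po2, 7.30, 48, p50st = 24)
    expect_equal(odc_po2(s, 7.30, 48, p50st = 24), po2, tolerance = 1e-6)
  }
})

test_that("oxygen content is the Hufner + dissolved form", {
  expect_equal(o2_content(0, 0, hb = 0), 0)
  # hand arithmetic: 1.34 * 9.30 * 0.94 + 0.003 * 69.0
  expect_equal(o2_content(69.0, 0.94, hb = 9.30), 11.92128, tolerance = 1e-8)
  # linear in Hb at fixed saturation when nothing is dissolved
  expect_equal(o2_content(0, 0.8, hb = 16), 2 * o2_content(0, 0.8, hb = 8))
  expect_equal(o2_content(100, 0.97, hb = 15, gas_constants(hufner = 1.39)),
               1.39 * 15 * 0.97 + 0.3)
})

test_that("CO2 content matches the oracle and shows the Haldane effect", {
  expect_equal(co2_content(0, 7.40, 0.97, 15), 0)
  expect_equal(co2_content(40, 7.40, 0.97, 15), co2_oracle(40, 7.40, 0.97, 15),
               tolerance = 1e-9)
  expect_equal(co2_content(40, 7.40, 0.97, 15), 45.28, tolerance = 1e-3)
  # Haldane: lower saturation carries more CO2 at the same PCO2
  expect_gt(co2_content(40, 7.40, 0.70, 15), co2_content(40, 7.40, 1.00, 15))
  # increasing in PCO2
  cc <- vapply(seq(10, 110, by = 10), co2_content, numeric(1),
               ph = 7.40, so2 = 0.97, hb = 15)
  expect_true(all(diff(cc) > 0))
})

test_that("Van Slyke relation recovers the normal point and is monotone", {
  expect_equal(acid_base_ph(40, be = 0, hb = 15), 7.40, tolerance = 0.01)
  expect_lt(acid_base_ph(80, be = 0), 7.40)
  expect_gt(acid_base_ph(20, be = 0), 7.40)
  expect_gt(acid_base_ph(40, be = 5), acid_base_ph(40, be = 0))
  expect_error(acid_base_ph(0), "positive")
  # forward and inverse agree with the independent oracle
  for (pc in c(25, 40, 70, 110)) {
    for (be in c(-6.5, 0, 4.9)) {
      ph <- acid_base_ph(pc, be, hb = 11)
      expect_equal(be_oracle(ph, pc, 11), be, tolerance = 1e-6)
      expect_equal(base_excess(ph, pc, hb = 11), be, tolerance = 1e-6)
    }
  }
})

test_that("pH spans a physiologic range over the input envelope", {
  ph <- c(acid_base_ph(111.6, -6.5, 6), acid_base_ph(23.8, 4.9, 17.3))
  expect_true(ph[1] > 6.8 && ph[2] < 7.8)
})

test_that("CO2 content inversion round-trips through contents", {
  bl <- blood_params(hb = 13, p50st = 25, be = -2)
  for (pco2 in c(30, 46, 75)) {
    ph <- acid_base_ph(pco2, bl$be, bl$hb)
    s <- odc_saturation(55, ph, pco2, bl$p50st)
    to2 <- o2_content(55, s, bl$hb)
    tco2 <- co2_content(pco2, ph, s, bl$hb)
    g <- blood_from_contents(to2, tco2, bl)
    expect_equal(g$pco2, pco2, tolerance = 1e-6)
    expect_equal(g$po2, 55, tolerance = 1e-6)
    expect_equal(g$ph, ph, tolerance = 1e-8)
  }
})

test_that("mixed venous state obeys the Fick principle", {
  bl <- blood_params(hb = 9.30)
  metab <- metabolic_state(vco2 = 187, r = 0.74, co = 5.25)
  expect_equal(metab$vo2, 252.7027, tolerance = 1e-6)
  expect_equal(metab$vo2 * metab$r, metab$vco2, tolerance = 1e-9)
  art <- list(cao2 = 11.92, caco2 = 45)
  ven <- mixed_venous(art, metab, bl)
  expect_equal(ven$cvo2, 11.92 - 252.7027 / 52.5, tolerance = 1e-6)
  expect_equal(ven$cvo2, 7.107, tolerance = 1e-3)
  expect_equal(ven$cvco2, 45 + 187 / 52.5, tolerance = 1e-9)
  # mass conservation: CO x content difference recovers VO2
  expect_equal(10 * metab$co * (art$cao2 - ven$cvo2), metab$vo2,
               tolerance = 1e-9)
  # zero metabolism leaves blood unchanged
  same <- mixed_venous(art, metabolic_state(1e-12, 1, 5), bl)
  expect_equal(same$cvo2, art$cao2, tolerance = 1e-9)
  # infeasible state aborts rather than clamping
  expect_error(mixed_venous(list(cao2 = 2, caco2 = 45),
                            metabolic_state(300, 0.8, 4), bl), "infeasible")
})
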