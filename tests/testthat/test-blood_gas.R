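test_that("dissociation curve matches the closed form and its P50", {
  # direct evaluation of 1/(1 + 23400/(p^3 + 150 p)) at standard pH/PCO2
  expect_equal(sat_from_po2(100, 7.40, 40),
               1 / (1 + 23400 / (100^3 + 150 * 100)), tolerance = 1e-12)
  expect_equal(sat_from_po2(100, 7.40, 40), 0.9775, tolerance = 1e-4)

  # independent P50 oracle: root of x^3 + 150 x = 23400 by bisection
  f <- function(x) x^3 + 150 * x - 23400
  lo <- 1; hi <- 100
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  p50 <- (lo + hi) / 2
  expect_equal(p50, 26.86, tolerance = 1e-3)
  expect_equal(sat_from_po2(p50, 7.40, 40), 0.5, tolerance = 1e-9)

  # asymptote and domain errors
  expect_gt(sat_from_po2(700, 7.40, 40), 0.999)
  expect_lt(sat_from_po2(1e5, 7.40, 40), 1)
  expect_error(sat_from_po2(0, 7.40, 40), "positive")
  expect_error(sat_from_po2(-5, 7.40, 40), "positive")
})

test_that("Bohr shift moves the curve in the physiological direction", {
  # acidosis and hypercapnia both lower saturation at fixed PO2
  expect_lt(sat_from_po2(60, 7.20, 40), sat_from_po2(60, 7.40, 40))
  expect_lt(sat_from_po2(60, 7.40, 60), sat_from_po2(60, 7.40, 40))
  expect_gt(sat_from_po2(60, 7.55, 40), sat_from_po2(60, 7.40, 40))
})

test_that("saturation is strictly increasing in PO2 across the range", {
  for (cond in list(c(7.40, 40), c(7.24, 62), c(7.55, 25))) {
    grid <- seq(1, 800, length.out = 120)
    s <- sat_from_po2(grid, cond[1], cond[2])
    expect_true(all(diff(s) > 0))
    expect_true(all(s > 0 & s < 1))
  }
})

test_that("PO2/saturation inversion round-trips below 0.01 mmHg", {
  expect_equal(po2_from_sat(0.5, 7.40, 40), 26.86, tolerance = 1e-3)
  expect_equal(po2_from_sat(0.9775, 7.40, 40), 100, tolerance = 1e-3)
  for (p in seq(20, 150, by = 10)) {
    rt <- po2_from_sat(sat_from_po2(p, 7.4, 40), 7.4, 40)
    expect_lt(abs(rt - p), 0.01)
  }
  expect_error(po2_from_sat(0), "strictly between")
  expect_error(po2_from_sat(1), "strictly between")
})

test_that("oxygen content follows Huefner plus dissolved and is bilinear", {
  expect_equal(o2_content(10, 0.84, 52), 1.34 * 10 * 0.84 + 0.0031 * 52,
               tolerance = 1e-12)
  expect_equal(o2_content(10, 0.84, 52), 11.42, tolerance = 1e-2)
  expect_equal(o2_content(14, 1.0, 100), 19.07, tolerance = 1e-2)
  expect_equal(o2_content(10, 0, 0), 0)
  # exact superposition in hb and in sat
  expect_equal(o2_content(7, 0.6, 0) + o2_content(3, 0.6, 0),
               o2_content(10, 0.6, 0), tolerance = 1e-12)
  expect_equal(o2_content(10, 0.25, 0) + o2_content(10, 0.5, 0),
               o2_content(10, 0.75, 0), tolerance = 1e-12)
  expect_error(o2_content(-1, 0.5, 40), "hb")
})

test_that("CO2 content reproduces the Douglas whole-blood arithmetic", {
  # independent oracle: dissolved + bicarbonate plasma content, converted to
  # mL/dL, times the hemoglobin/saturation correction, all spelled out
  plasma_mmol <- 0.0307 * 40 * (1 + 10^(7.40 - 6.1))
  corr <- 1 - 0.0289 * 15 / ((3.352 - 0.456 * 0.975) * (8.142 - 7.40))
  oracle <- 2.226 * plasma_mmol * corr
  expect_equal(co2_content(40, 7.40, 15, 0.975), oracle, tolerance = 1e-12)
  expect_equal(oracle, 45.77, tolerance = 1e-2)

  # limits and monotonicity
  expect_lt(co2_content(1e-6, 7.9, 15, 0.975), 1e-3)
  expect_gt(co2_content(45, 7.40, 15, 0.975), co2_content(40, 7.40, 15, 0.975))
  grid <- seq(10, 90, by = 5)
  cc <- vapply(grid, co2_content, numeric(1), ph = 7.40, hb = 15, sat = 0.975)
  expect_true(all(diff(cc) > 0))
  expect_error(co2_content(40, 8.3, 15, 0.975), "ph")
})

test_that("Haldane effect: oxygenated blood carries less CO2", {
  for (pco2 in c(30, 40, 60)) {
    expect_lt(co2_content(pco2, 7.4, 15, 1.0), co2_content(pco2, 7.4, 15, 0.5))
    expect_lt(co2_content(pco2, 7.3, 10, 1.0), co2_content(pco2, 7.3, 10, 0.5))
  }
})

test_that("CO2 content inversion round-trips below 0.01 mmHg", {
  for (pco2 in c(20, 35, 40, 60, 80)) {
    c0 <- co2_content(pco2, 7.4, 15, 0.975)
    expect_lt(abs(pco2_from_co2_content(c0, 7.4, 15, 0.975) - pco2), 0.01)
  }
  expect_equal(pco2_from_co2_content(45.77, 7.4, 15, 0.975), 40,
               tolerance = 1e-2)
  expect_error(pco2_from_co2_content(-1, 7.4, 15, 0.975), "positive")
})

test_that("Henderson-Hasselbalch closure gives the textbook pH", {
  expect_equal(ph_from_pco2(40, 24), 6.1 + log10(24 / (0.0307 * 40)),
               tolerance = 1e-12)
  expect_equal(ph_from_pco2(40, 24), 7.39, tolerance = 5e-3)
  expect_equal(ph_from_pco2(35, 20.3), 7.38, tolerance = 1e-2)
  # doubling PCO2 at fixed bicarbonate drops pH by log10(2)
  expect_equal(ph_from_pco2(40, 24) - ph_from_pco2(80, 24), log10(2),
               tolerance = 1e-12)
  expect_error(ph_from_pco2(0, 24), "positive")
})

test_that("blood_state derives contents consistently and validates inputs", {
  b <- blood_state(po2 = 52, pco2 = 35, ph = 7.38, hb = 10)
  expect_equal(b$o2_content, o2_content(10, b$sat, 52))
  expect_equal(b$co2_content, co2_content(35, 7.38, 10, b$sat))
  expect_gte(b$o2_content, 0.003 * b$po2 * (1 - 1e-6))
  expect_error(blood_state(po2 = -1, pco2 = 40, ph = 7.4, hb = 10),
               "positive")
  expect_error(blood_state(po2 = 100, pco2 = 40, ph = 7.4, hb = 1), "hb")
})
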