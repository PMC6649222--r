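test_that("flow partition clamps at the cardiac output", {
  p <- proto_patient()
  f <- partition_flows(p, proto_ecmo())
  expect_equal(f$drained, 4.9)
  expect_equal(f$bypassing, 5.1)
  f0 <- partition_flows(p, no_ecmo())
  expect_equal(f0$drained, 0)
  expect_equal(f0$bypassing, 10)
  fc <- partition_flows(p, proto_ecmo(blood_flow = 12))
  expect_equal(fc$drained, 10)
  expect_equal(fc$bypassing, 0)
  # recirculation shrinks the effective flow before the clamp
  fr <- partition_flows(p, proto_ecmo(recirculation_fraction = 0.2))
  expect_equal(fr$drained, 4.9 * 0.8)
})

test_that("stream mixing is a flow-weighted content mean", {
  a <- blood_state(100, 40, 7.40, 10)
  b <- blood_state(30, 50, 7.31, 10)
  m <- mix_streams(list(list(flow = 4.9, blood = a), list(flow = 5.1, blood = b)))
  expect_equal(m$o2_content,
               (4.9 * a$o2_content + 5.1 * b$o2_content) / 10,
               tolerance = 1e-6)
  expect_equal(m$co2_content,
               (4.9 * a$co2_content + 5.1 * b$co2_content) / 10,
               tolerance = 1e-6)
  expect_true(m$po2 > b$po2 && m$po2 < a$po2)

  # idempotence (for a state consistent with the acid-base closure) and
  # commutativity; content idempotence holds for any state
  ac <- blood_state(100, 40, ph_from_pco2(40, 24), 10)
  mm <- mix_streams(list(list(flow = 2, blood = ac), list(flow = 3, blood = ac)))
  expect_equal(mm$po2, ac$po2, tolerance = 1e-4)
  expect_equal(mm$pco2, ac$pco2, tolerance = 1e-4)
  mc <- mix_streams(list(list(flow = 2, blood = a), list(flow = 3, blood = a)))
  expect_equal(mc$o2_content, a$o2_content, tolerance = 1e-9)
  expect_equal(mc$co2_content, a$co2_content, tolerance = 1e-9)
  m2 <- mix_streams(list(list(flow = 5.1, blood = b), list(flow = 4.9, blood = a)))
  expect_equal(m$po2, m2$po2, tolerance = 1e-9)

  expect_error(mix_streams(list()), "no streams")
  expect_error(mix_streams(list(list(flow = 0, blood = a))), "total flow")
  c_hb <- blood_state(100, 40, 7.40, 12)
  expect_error(mix_streams(list(list(flow = 1, blood = a),
                                list(flow = 1, blood = c_hb))), "hemoglobin")
})

test_that("complete shunt passes pulmonary-artery blood through unchanged", {
  pa <- blood_state(45, 48, 7.33, 10)
  art <- lung_exchange(pa, ultraprotective_vent(), proto_patient(shunt_fraction = 1))
  expect_identical(art, pa)
})

test_that("zero shunt equilibrates arterial blood to alveolar gas", {
  pa <- blood_state(45, 48, 7.33, 10)
  v <- ultraprotective_vent(fio2 = 1.0, dead_space = 100)
  art <- lung_exchange(pa, v, proto_patient(shunt_fraction = 0))
  expect_equal(art$po2, alveolar_po2(1.0, art$pco2), tolerance = 0.05)
  expect_gt(art$sat, 0.999)
})

test_that("partial shunt mixes contents in the shunt proportion", {
  pa <- blood_state(45, 48, 7.33, 10)
  p <- proto_patient(shunt_fraction = 0.95)
  v <- ultraprotective_vent(dead_space = 132)
  art <- lung_exchange(pa, v, p)
  # recover the implied capillary content from the mixing identity
  cap_o2 <- (art$o2_content - 0.95 * pa$o2_content) / 0.05
  expect_gt(cap_o2, pa$o2_content)
  expect_lt(art$o2_content, cap_o2)
  expect_gt(art$o2_content, pa$o2_content)
})

test_that("native-lung CO2 clearance balances alveolar ventilation", {
  pa <- blood_state(45, 48, 7.33, 10)
  # with zero shunt the arterial blood IS the end-capillary blood, so the
  # solved alveolar PCO2 is directly observable as the arterial PCO2
  p <- proto_patient(shunt_fraction = 0)
  v <- protective_vent(dead_space = 130)
  art <- lung_exchange(pa, v, p)
  removal <- p$cardiac_output * 10 * (pa$co2_content - art$co2_content)
  va <- alveolar_ventilation(v)
  expect_equal(removal, va * 1000 * art$pco2 / 713, tolerance = 1e-4)
  expect_lt(art$pco2, pa$pco2)
})

test_that("tissue exchange applies the Fick principle exactly", {
  art <- blood_state(100, 40, 7.40, 10)
  ven <- tissue_exchange(art, proto_patient())
  expect_equal(art$o2_content - ven$o2_content, 2.0, tolerance = 1e-6)
  expect_equal(ven$co2_content - art$co2_content, 1.6, tolerance = 1e-6)
  ven2 <- tissue_exchange(art, proto_patient(cardiac_output = 5.5))
  expect_equal(art$o2_content - ven2$o2_content, 200 / 55, tolerance = 1e-6)
  ven3 <- tissue_exchange(art, proto_patient(vo2 = 1e-9))
  expect_equal(ven3$o2_content, art$o2_content, tolerance = 1e-6)
})

test_that("oxygen demand beyond delivery raises a typed infeasibility", {
  art <- blood_state(30, 40, 7.40, 2.5) # profoundly anemic and hypoxemic
  expect_error(tissue_exchange(art, proto_patient(hb = 2.5, vo2 = 500)),
               class = "ecmosim_infeasible")
})

test_that("healthy lungs without ECMO supply all oxygen through the lung", {
  p <- proto_patient(shunt_fraction = 0.03, hb = 14, cardiac_output = 5,
                     vo2 = 250, vco2 = 200)
  v <- vent_settings(mode = "VCV", peep = 5, vt_ml = 500, rr = 12, cst = 50,
                     fio2 = 0.4, dead_space = 150)
  ss <- solve_steady_state(p, v, no_ecmo())
  expect_true(ss$converged)
  expect_gt(ss$arterial$sat, 0.97)
  expect_equal(ss$ecmo_o2_transfer, 0)
  expect_equal(ss$lung_o2_transfer, 250, tolerance = 0.5)
  expect_equal(ss$lung_vco2, 200, tolerance = 0.5)
})

test_that("prototypical on-ECMO patient converges with matched O2 transfer", {
  ss <- solve_steady_state(proto_patient(), ultraprotective_vent(),
                           proto_ecmo())
  expect_true(ss$converged)
  expect_false(ss$infeasible)
  expect_equal(ss$ecmo_o2_transfer + ss$lung_o2_transfer, 200,
               tolerance = 0.5)
  expect_equal(ss$ecmo_vco2 + ss$lung_vco2, 160, tolerance = 0.5)
  expect_gt(ss$ecmo_o2_transfer, ss$lung_o2_transfer) # circuit dominates
  # Fick conservation stated on the converged states themselves
  q10 <- 100
  expect_lt(abs(q10 * (ss$arterial$o2_content - ss$mixed_venous$o2_content) -
                  200), 0.5)
  expect_lt(abs(q10 * (ss$mixed_venous$co2_content - ss$arterial$co2_content) -
                  160), 0.5)
})

test_that("total shunt without ECMO is flagged infeasible, not solved", {
  ss <- solve_steady_state(proto_patient(shunt_fraction = 1),
                           ultraprotective_vent(), no_ecmo())
  expect_false(ss$converged)
  expect_true(ss$infeasible)
  expect_match(ss$message, "demand exceeds delivery")
})

test_that("the solver is deterministic", {
  a <- solve_steady_state(proto_patient(), ultraprotective_vent(), proto_ecmo())
  b <- solve_steady_state(proto_patient(), ultraprotective_vent(), proto_ecmo())
  expect_identical(summary(a), summary(b))
})
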