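test_that("breath timing splits the cycle into Ti = VT/flow + pause and Te", {
  bt <- breath_timing(vent_settings(400, 60, 0.4, 20, 5))
  expect_equal(unname(bt), c(0.8, 2.2))

  bt0 <- breath_timing(vent_settings(0, 60, 0, 20, 5))
  expect_equal(unname(bt0), c(0, 3.0))

  # 580 mL at 1 L/s plus the 0.4 s pause: Ti 0.98 s, Te 60/35 - 0.98
  bt2 <- breath_timing(vent_settings(580, 60, 0.4, 35, 5))
  expect_equal(unname(bt2), c(0.98, 60 / 35 - 0.98), tolerance = 1e-12)

  # a breath that cannot be exhaled in the cycle is rejected at construction
  expect_error(vent_settings(1600, 60, 0.4, 35), "expiratory time")
})

test_that("auto-PEEP closed form matches breath-by-breath iteration", {
  s20 <- vent_settings(400, 60, 0.4, 20, 5)
  lung60 <- lung_circuit(60)
  ap <- auto_peep(s20, lung60)
  expect_equal(ap, auto_peep_by_iteration(400, 2.2, 60, 5), tolerance = 1e-8)
  expect_lt(abs(ap - 0.004), 0.001)

  s35 <- vent_settings(400, 60, 0.4, 35, 5)
  ap35 <- auto_peep(s35, lung60)
  expect_equal(ap35, auto_peep_by_iteration(400, 60 / 35 - 0.8, 60, 5),
               tolerance = 1e-8)
  expect_lt(abs(ap35 - 0.32), 0.02)

  # complete-exhalation limit: Te/tau > 20 means no trapping
  expect_lt(auto_peep(s20, lung_circuit(10, 5)), 1e-6)

  # 100 random valid parameter sets, 1e-6 cmH2O agreement
  set.seed(42)
  for (i in 1:100) {
    vt <- runif(1, 100, 700)
    rr <- runif(1, 10, 35)
    C <- runif(1, 15, 80)
    r <- runif(1, 2, 25)
    flow <- runif(1, 30, 90)
    s <- vent_settings(vt, flow, runif(1, 0, 0.5), rr, 5)
    te <- breath_timing(s)[["t_exp"]]
    if (te <= 0.05) next
    expect_equal(auto_peep(s, lung_circuit(C, 5, r)),
                 auto_peep_by_iteration(vt, te, C, r),
                 tolerance = 1e-6)
  }
})

test_that("auto-PEEP rises with respiratory rate and expiratory resistance", {
  lung <- lung_circuit(60, 5, 15)
  aps <- vapply(seq(12, 35, by = 1), function(rr)
    auto_peep(vent_settings(400, 60, 0.4, rr, 5), lung), 0)
  expect_true(all(diff(aps) > 0))

  s <- vent_settings(400, 60, 0.4, 30, 5)
  apr <- vapply(seq(0, 30, by = 2), function(xr)
    auto_peep(s, lung, extra_exp_resistance = xr), 0)
  expect_true(all(diff(apr) > 0))
})

test_that("static pressures follow the one-compartment closed forms", {
  b <- simulate_breath(vent_settings(400, 60, 0.4, 20, 5), lung_circuit(60))
  expect_equal(b$p_plat, 5 + auto_peep(b$settings, b$lung) + 400 / 60)
  expect_equal(b$p_plat, 11.67, tolerance = 1e-3)
  expect_equal(b$p_peak, b$p_plat + 5 * 1)   # R 5 cmH2O/L/s at 1 L/s
  expect_equal(b$peep_total, 5, tolerance = 1e-2)

  # zero-volume breath: all pressures collapse to PEEP
  b0 <- simulate_breath(vent_settings(0, 60, 0, 20, 5), lung_circuit(60))
  expect_equal(c(b0$p_peak, b0$p_plat, b0$peep_total), c(5, 5, 5))

  # stiff lung at high PEEP
  b20 <- simulate_breath(vent_settings(400, 60, 0.4, 20, 15),
                         lung_circuit(20))
  expect_equal(b20$p_plat, 35, tolerance = 1e-3)
  expect_equal(b20$p_peak, 40, tolerance = 1e-3)

  # invariant chain
  expect_true(b20$p_peak >= b20$p_plat &&
                b20$p_plat >= b20$peep_total &&
                b20$peep_total >= 15)
})

test_that("resistive and elastic pressure components are exact", {
  set.seed(7)
  for (i in 1:20) {
    s <- vent_settings(runif(1, 200, 600), runif(1, 40, 90), 0.3,
                       runif(1, 10, 25), runif(1, 0, 15))
    lung <- lung_circuit(runif(1, 15, 80), runif(1, 2, 20))
    xr <- runif(1, 0, 10)
    b <- simulate_breath(s, lung, extra_resistance_insp = xr)
    expect_equal(b$p_peak - b$p_plat,
                 (lung$resistance_insp + xr) * s$flow / 60)
    expect_equal(b$p_plat - b$peep_total, s$tidal_volume / lung$compliance)
  }
})

test_that("waveform integrates back to the set tidal volume", {
  for (vt in c(150, 400, 580)) {
    b <- simulate_breath(vent_settings(vt, 60, 0.4, 20, 5), lung_circuit(40))
    expect_lt(abs(b$delivered_vt - vt) / vt, 0.005)
    expect_named(b$waveform,
                 c("time_s", "flow_Lps", "pressure_cmH2O", "volume_mL"))
    # waveform peak pressure agrees with the static Ppeak
    expect_equal(max(b$waveform$pressure_cmH2O), b$p_peak)
  }
})

test_that("waveform export writes a tidy one-breath CSV", {
  b <- simulate_breath(vent_settings(), lung_circuit(60))
  f <- withr::local_tempfile(fileext = ".csv")
  write_waveform(b, f)
  back <- read.csv(f)
  expect_equal(names(back),
               c("time_s", "flow_Lps", "pressure_cmH2O", "volume_mL"))
  expect_equal(nrow(back), nrow(b$waveform))
})
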