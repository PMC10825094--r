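test_that("titration reproduces the consistent bench endpoints", {
  devs <- calibrated_devices()
  base <- vent_settings()
  lung <- lung_circuit(40)

  tv100 <- titrate("VT", devs[["ANA-100"]], base, lung)
  expect_equal(tv100$final_vt, 580)
  expect_equal(tv100$steps$setting, c(400, 460, 520, 580))

  tv50 <- titrate("VT", devs[["ANA-50"]], base, lung)
  expect_equal(tv50$final_vt, 520)

  tr50 <- titrate("RR", devs[["ANA-50"]], base, lung)
  expect_equal(tr50$final_rr, 29)
  expect_equal(tr50$steps$setting, c(20, 23, 26, 29))

  trm <- titrate("RR", devs[["MIRUS"]], base, lung)
  expect_equal(trm$final_rr, 35)

  # no device: already on target, zero steps, within band
  t0 <- titrate("VT", NULL, base, lung)
  expect_equal(t0$n_steps, 0)
  expect_equal(t0$final_vt, 400)
  expect_true(t0$within_band)
})

test_that("controller endpoint equals the exhaustive grid-scan oracle", {
  devs <- calibrated_devices()
  base <- vent_settings()
  lung <- lung_circuit(40)
  for (d in devs) for (mode in c("VT", "RR")) {
    got <- titrate(mode, d, base, lung)
    want <- titration_endpoint_by_scan(mode, 120 + d$effective_dead_space)
    expect_equal(if (mode == "VT") got$final_vt else got$final_rr, want,
                 info = paste(d$name, mode))
  }
})

test_that("EtCO2 decreases strictly along steps and steps order with dead space", {
  devs <- calibrated_devices()
  base <- vent_settings()
  lung <- lung_circuit(40)
  n_steps <- sapply(c("VT", "RR"), function(mode)
    sapply(devs[c("ANA-50", "MIRUS", "ANA-100")], function(d) {
      tr <- titrate(mode, d, base, lung)
      expect_true(all(diff(tr$steps$etco2) < 0))
      expect_lte(tr$final_etco2, 42)
      expect_equal(tr$within_band, tr$final_etco2 >= 38)
      tr$n_steps
    }))
  # more effective dead space never takes fewer steps
  expect_true(all(apply(n_steps, 2, function(x) all(diff(x) >= 0))))
})

test_that("overshoot is surfaced, not hidden: ANA-50 VT arm lands below band", {
  tr <- titrate("VT", calibrated_devices()[["ANA-50"]], vent_settings(),
                lung_circuit(40))
  expect_false(tr$within_band)
  expect_equal(tr$final_etco2, 36.4, tolerance = 0.05)
})

test_that("exceeding max_steps errors with the trajectory attached", {
  # an absurd dead space that RR steps cannot correct within the cap
  dev <- sedation_device("huge", 0, effective_dead_space = 270)
  err <- tryCatch(
    titrate("RR", dev, vent_settings(), lung_circuit(40), max_steps = 5),
    error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "titration failed")
  expect_s3_class(err$trajectory, "data.frame")
  expect_gt(nrow(err$trajectory), 1)
})

test_that("dwell-based dynamic titration agrees with steady-state endpoints", {
  devs <- calibrated_devices()
  for (d in devs) for (mode in c("VT", "RR")) {
    ss <- titrate(mode, d, vent_settings(), lung_circuit(40))
    dy <- titrate(mode, d, vent_settings(), lung_circuit(40),
                  dynamics = TRUE)
    expect_equal(dy$final_vt, ss$final_vt, info = paste(d$name, mode))
    expect_equal(dy$final_rr, ss$final_rr, info = paste(d$name, mode))
  }
})

test_that("mechanics are re-simulated at the final settings", {
  tr <- titrate("RR", calibrated_devices()[["MIRUS"]], vent_settings(),
                lung_circuit(40))
  expect_equal(tr$mechanics$p_plat,
               tr$mechanics$peep_total + 400 / 40)
  expect_equal(tr$final_settings$rate, 35)
  # higher rate shortens Te: auto-PEEP must exceed the baseline value
  expect_gt(tr$mechanics$auto_peep,
            auto_peep(vent_settings(), lung_circuit(40)))
})
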