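# Independent oracles used across test files. They deliberately avoid the
# closed forms in the package: auto-PEEP by breath-by-breath iteration,
# titration by exhaustive grid scan, washout by explicit CO2 mass balance.

# iterate passive exhalation breath by breath until the end-expiratory
# trapped volume reaches a fixed point; returns auto-PEEP in cmH2O
auto_peep_by_iteration <- function(vt_ml, te_s, c_ml, r_exp,
                                   max_breaths = 200, tol_l = 1e-9) {
  c_l <- c_ml / 1000
  tau <- r_exp * c_l
  if (tau <= 0) return(0)
  v <- 0
  for (i in seq_len(max_breaths)) {
    v_new <- (v + vt_ml / 1000) * exp(-te_s / tau)
    if (abs(v_new - v) < tol_l) {
      v <- v_new
      break
    }
    v <- v_new
  }
  v / c_l
}

# exhaustive scan of the titration grid: first setting value whose
# steady-state EtCO2 satisfies the stop rule EtCO2 <= target + band
titration_endpoint_by_scan <- function(mode, vd_total, base_vt = 400,
                                       base_rr = 20, vd_circuit = 120,
                                       target = 40, band = 2, step_vt = 60,
                                       step_rr = 3, k_max = 60) {
  base_va <- base_rr * (base_vt - vd_circuit)
  for (k in 0:k_max) {
    vt <- if (mode == "VT") base_vt + k * step_vt else base_vt
    rr <- if (mode == "RR") base_rr + k * step_rr else base_rr
    et <- target * base_va / (rr * (vt - vd_total))
    if (et <= target + band) return(if (mode == "VT") vt else rr)
  }
  NA_real_
}

# explicit per-breath CO2 mass balance on a well-mixed compartment:
# inflow q per breath, removal = current fraction times per-breath VA
washout_by_mass_balance <- function(et0, va_new, baseline_et, baseline_va,
                                    frc, rr, n_breaths) {
  q_per_breath <- baseline_et * baseline_va / rr   # mmHg * mL per breath
  va_b <- va_new / rr
  et <- numeric(n_breaths)
  cur <- et0
  for (i in seq_len(n_breaths)) {
    cur <- cur + (q_per_breath - cur * va_b) / frc
    et[i] <- cur
  }
  et
}

calibrated_devices <- function() calibrate_devices()$devices
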