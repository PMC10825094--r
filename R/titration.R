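#' EtCO2-correction titration
#'
#' Reproduces the bench protocol: after a device raises EtCO2 above the
#' target band, either tidal volume or respiratory rate is raised in fixed
#' 15%-of-baseline increments (60 mL or 3 breaths/min from the 400 mL /
#' 20 min^-1 baseline) until EtCO2 is corrected. Because the grid is fixed,
#' EtCO2 can jump from above 42 mmHg straight below 38 mmHg; the controller
#' therefore stops at the FIRST grid value with EtCO2 <= target + band (the
#' only monotone stop rule that always terminates) and reports overshoot via
#' `within_band` instead of hiding it.
#'
#' Steady-state mode (default) evaluates the closed-form EtCO2 at each step.
#' With `dynamics = TRUE`, each step dwells for `dwell_min` minutes of
#' per-breath washout ([washout_to_steady_state()]) and the stop rule is
#' applied to the end-of-dwell value.
#'
#' @param mode `"VT"` or `"RR"`: which setting is raised.
#' @param device A calibrated [sedation_device()] (non-`NA`
#'   `effective_dead_space`), or `NULL` for a no-device control run.
#' @param base Baseline [vent_settings()] (EtCO2 on target without the
#'   device).
#' @param lung [lung_circuit()] providing compliance, resistances and the
#'   circuit dead space.
#' @param target,band Target EtCO2 and half-band (mmHg), default 40 +/- 2.
#' @param step_vt,step_rr Increments (mL, breaths/min), default 60 and 3.
#' @param max_steps Safety cap, default 20; exceeding it is an error
#'   carrying the trajectory.
#' @param dynamics Logical; honor the per-step dwell with breath-by-breath
#'   washout.
#' @param frc Compartment volume for washout dynamics (mL), default 2500.
#' @param dwell_min Dwell per step (min), default 2.5.
#' @return Object of class `titration_result`: `mode`, `steps` (data frame
#'   of setting value and steady EtCO2, step 0 = with-device baseline),
#'   `final_vt`, `final_rr`, `final_etco2`, `n_steps`, `within_band`,
#'   `final_settings` ([vent_settings()]), `mechanics` (re-simulated breath
#'   at the final settings), `total_dead_space`.
#' @examples
#' cal <- calibrate_devices()
#' titrate("VT", cal$devices[["ANA-100"]], vent_settings(), lung_circuit(40))
#' @export
titrate <- function(mode = c("VT", "RR"), device, base = vent_settings(),
                    lung = lung_circuit(40), target = 40, band = 2,
                    step_vt = 60, step_rr = 3, max_steps = 20,
                    dynamics = FALSE, frc = 2500, dwell_min = 2.5) {
  mode <- match.arg(mode)
  vd_added <- if (is.null(device)) 0 else device$effective_dead_space
  if (is.na(vd_added))
    stop("device has no calibrated effective_dead_space; run ",
         "calibrate_devices() first", call. = FALSE)
  vd_total <- lung$dead_space + vd_added

  base_va <- alveolar_ventilation(base$rate, base$tidal_volume,
                                  lung$dead_space)
  anchor <- gas_state(target, base_va)

  settings_at <- function(k) {
    if (mode == "VT")
      vent_settings(base$tidal_volume + k * step_vt, base$flow, base$pause,
                    base$rate, base$peep, base$fio2)
    else
      vent_settings(base$tidal_volume, base$flow, base$pause,
                    base$rate + k * step_rr, base$peep, base$fio2)
  }
  etco2_at <- function(s) {
    va <- alveolar_ventilation(s$rate, s$tidal_volume, vd_total)
    steady_state_etco2(va, anchor)
  }

  k <- 0
  s <- settings_at(0)
  cur_ss <- etco2_at(s)
  cur <- cur_ss
  if (dynamics) {
    w <- washout_to_steady_state(
      anchor, alveolar_ventilation(s$rate, s$tidal_volume, vd_total),
      frc = frc, rr = s$rate, n_breaths = ceiling(dwell_min * s$rate))
    cur <- w[length(w)]
  }
  value_of <- function(s) if (mode == "VT") s$tidal_volume else s$rate
  steps <- data.frame(step = 0, setting = value_of(s), etco2 = cur)

  while (cur > target + band) {
    if (k >= max_steps) {
      err <- simpleError(paste0("titration failed: EtCO2 still ",
                                round(cur, 1), " mmHg after ", k, " steps"))
      err$trajectory <- steps
      stop(err)
    }
    k <- k + 1
    prev <- cur
    s <- settings_at(k)
    if (dynamics) {
      state_k <- gas_state(prev, anchor$alveolar_ventilation,
                           baseline_etco2 = anchor$baseline_etco2,
                           baseline_alveolar_ventilation =
                             anchor$baseline_alveolar_ventilation)
      w <- washout_to_steady_state(
        state_k, alveolar_ventilation(s$rate, s$tidal_volume, vd_total),
        frc = frc, rr = s$rate, n_breaths = ceiling(dwell_min * s$rate))
      cur <- w[length(w)]
    } else {
      cur <- etco2_at(s)
    }
    steps <- rbind(steps, data.frame(step = k, setting = value_of(s),
                                     etco2 = cur))
  }

  mech <- simulate_breath(
    s, lung,
    extra_resistance_insp = if (is.null(device)) 0 else device$resistance_insp,
    extra_resistance_exp = if (is.null(device)) 0 else device$resistance_exp)

  structure(list(mode = mode,
                 device = if (is.null(device)) "CTRL" else device$name,
                 steps = steps, final_vt = s$tidal_volume,
                 final_rr = s$rate, final_etco2 = cur, n_steps = k,
                 within_band = abs(cur - target) <= band,
                 final_settings = s, mechanics = mech,
                 total_dead_space = vd_total),
            class = "titration_result")
}

#' @export
print.titration_result <- function(x, ...) {
  cat(sprintf("EtCO2 titration, %s arm, %s mode: %d step(s)\n",
              x$device, x$mode, x$n_steps))
  print(transform(x$steps, etco2 = round(etco2, 1)), row.names = FALSE)
  cat(sprintf("  final VT %g mL, RR %g/min, EtCO2 %.1f mmHg (%s band)\n",
              x$final_vt, x$final_rr, x$final_etco2,
              if (x$within_band) "within" else "OUTSIDE"))
  invisible(x)
}
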