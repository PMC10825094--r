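#' Auto-PEEP from incomplete passive exhalation
#'
#' Periodic steady state of single-exponential passive exhalation with time
#' constant tau = R_exp * C. The trapped end-expiratory volume is
#' `VT * exp(-Te/tau) / (1 - exp(-Te/tau))` and auto-PEEP is that volume over
#' the compliance. Tends to zero as Te/tau grows (complete exhalation).
#'
#' @param settings A [vent_settings()] object.
#' @param lung A [lung_circuit()] object.
#' @param extra_exp_resistance Additional expiratory resistance in series
#'   (cmH2O/L/s), e.g. from a device; default 0.
#' @return Auto-PEEP (cmH2O), >= 0.
#' @examples
#' auto_peep(vent_settings(rate = 35), lung_circuit(60))
#' @export
auto_peep <- function(settings, lung, extra_exp_resistance = 0) {
  bt <- breath_timing(settings)
  te <- bt[["t_exp"]]
  if (te <= 0) stop("invalid settings: expiratory time <= 0", call. = FALSE)
  c_l <- lung$compliance / 1000              # L/cmH2O
  tau <- (lung$resistance_exp + extra_exp_resistance) * c_l
  vt_l <- settings$tidal_volume / 1000
  if (tau <= 0 || vt_l == 0) return(0)
  r <- exp(-te / tau)
  v_trap <- vt_l * r / (1 - r)
  unname(v_trap / c_l)
}

#' Simulate one steady-state volume-controlled breath
#'
#' Computes the static pressures of the idealized one-compartment model --
#' total PEEP (set PEEP + auto-PEEP), plateau pressure `PEEPt + VT/C`, and
#' peak pressure `Pplat + R_insp * flow` -- and samples the full
#' flow/pressure/volume waveform of one breath at periodic steady state.
#' Exact phase-boundary samples are inserted so that trapezoidal integration
#' of the inspiratory flow recovers the set tidal volume exactly.
#'
#' During expiration the modeled airway pressure equals the set PEEP: for a
#' linear compartment the elastic recoil above PEEP is dissipated exactly
#' across the expiratory resistance that defines the time constant.
#'
#' @inheritParams auto_peep
#' @param extra_resistance_insp,extra_resistance_exp Additional series
#'   resistances (cmH2O/L/s), default 0. Pressures are modeled at a
#'   transducer distal to any device, so device resistance is excluded
#'   unless explicitly supplied.
#' @param sample_rate Waveform sampling rate (Hz), default 200.
#' @return An object of class `breath_mechanics`: `p_peak`, `p_plat`,
#'   `peep_total`, `auto_peep` (cmH2O), `t_insp`, `t_exp` (s),
#'   `delivered_vt` (mL, trapezoidal integral of inspiratory flow), and
#'   `waveform`, a data frame with columns `time_s`, `flow_Lps`,
#'   `pressure_cmH2O`, `volume_mL`.
#' @examples
#' b <- simulate_breath(vent_settings(), lung_circuit(60))
#' b$p_plat   # 11.67 cmH2O: PEEP 5 + 400/60
#' @export
simulate_breath <- function(settings, lung,
                            extra_resistance_insp = 0,
                            extra_resistance_exp = 0,
                            sample_rate = 200) {
  stopifnot(inherits(settings, "vent_settings") || is.list(settings),
            inherits(lung, "lung_circuit") || is.list(lung))
  bt <- breath_timing(settings)
  t_insp <- bt[["t_insp"]]; t_exp <- bt[["t_exp"]]
  if (t_exp <= 0) stop("invalid settings: expiratory time <= 0", call. = FALSE)

  vt <- settings$tidal_volume                       # mL
  c_ml <- lung$compliance                           # mL/cmH2O
  flow_lps <- lpm_to_lps(settings$flow)
  r_insp <- lung$resistance_insp + extra_resistance_insp
  r_exp <- lung$resistance_exp + extra_resistance_exp

  ap <- auto_peep(settings, lung, extra_resistance_exp)
  peep_total <- settings$peep + ap
  p_plat <- peep_total + vt / c_ml
  p_peak <- if (vt > 0) p_plat + r_insp * flow_lps else p_plat

  t_flow <- vt / 1000 / flow_lps                    # duration of the square
  cycle <- t_insp + t_exp
  dt <- 1 / sample_rate
  v_trap <- ap * c_ml                               # mL above relaxation at PEEP
  tau <- r_exp * c_ml / 1000                        # s

  grid_to <- function(a, b) {                       # [a, b] incl. both ends
    g <- seq(a, b, by = dt)
    if (g[length(g)] < b) g <- c(g, b)
    g
  }

  if (vt > 0) {
    ti1 <- grid_to(0, t_flow)
    insp <- data.frame(
      time_s = ti1,
      flow_Lps = flow_lps,
      pressure_cmH2O = peep_total + (flow_lps * ti1 * 1000) / c_ml +
        r_insp * flow_lps,
      volume_mL = v_trap + flow_lps * ti1 * 1000)
  } else {
    insp <- data.frame(time_s = 0, flow_Lps = 0,
                       pressure_cmH2O = peep_total, volume_mL = v_trap)
  }
  pause <- if (settings$pause > 0) {
    tp <- grid_to(t_flow, t_insp)
    data.frame(time_s = tp, flow_Lps = 0, pressure_cmH2O = p_plat,
               volume_mL = v_trap + vt)
  } else NULL
  te_rel <- grid_to(0, t_exp)
  if (tau > 0) {
    v_exp <- (vt + v_trap) * exp(-te_rel / tau)
    f_exp <- -(v_exp / 1000) / tau
  } else {
    v_exp <- c(vt + v_trap, rep(v_trap, length(te_rel) - 1))
    f_exp <- rep(0, length(te_rel))
  }
  expn <- data.frame(time_s = t_insp + te_rel, flow_Lps = f_exp,
                     pressure_cmH2O = settings$peep, volume_mL = v_exp)
  wf <- rbind(insp, pause, expn)
  rownames(wf) <- NULL

  ins <- wf$time_s <= t_flow + 1e-12 & wf$flow_Lps > 0
  delivered <- if (any(ins)) {
    tt <- wf$time_s[ins]; ff <- wf$flow_Lps[ins]
    sum(diff(tt) * (head(ff, -1) + ff[-1]) / 2) * 1000
  } else 0

  structure(list(p_peak = p_peak, p_plat = p_plat, peep_total = peep_total,
                 auto_peep = ap, t_insp = t_insp, t_exp = t_exp,
                 delivered_vt = delivered, settings = settings, lung = lung,
                 waveform = wf),
            class = "breath_mechanics")
}

#' @export
print.breath_mechanics <- function(x, digits = 2, ...) {
  cat("Steady-state breath mechanics (one-compartment, square flow)\n")
  cat(sprintf("  Ppeak %.*f | Pplat %.*f | PEEPt %.*f | auto-PEEP %.*f cmH2O\n",
              digits, x$p_peak, digits, x$p_plat, digits, x$peep_total,
              digits, x$auto_peep))
  cat(sprintf("  Ti %.3f s, Te %.3f s, delivered VT %.1f mL\n",
              x$t_insp, x$t_exp, x$delivered_vt))
  invisible(x)
}

#' Export a one-breath waveform as tidy CSV
#'
#' @param breath A `breath_mechanics` object from [simulate_breath()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(breath, path) {
  stopifnot(inherits(breath, "breath_mechanics"))
  utils::write.csv(breath$waveform, path, row.names = FALSE)
  invisible(path)
}

# head() used on numeric vectors above
#' @importFrom utils head
NULL
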