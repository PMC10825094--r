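#' End-tidal CO2 state anchored at a measured baseline
#'
#' The bench delivers a constant CO2 inflow into the alveolar compartment, so
#' at steady state `EtCO2 * VA` is conserved: end-tidal CO2 is inversely
#' proportional to alveolar ventilation. A `gas_state` stores the current
#' operating point together with the baseline anchor (40 mmHg at the baseline
#' alveolar ventilation in the default protocol).
#'
#' @param etco2 Current EtCO2 (mmHg), > 0.
#' @param alveolar_ventilation Current alveolar ventilation (mL/min), > 0.
#' @param baseline_etco2 Anchor EtCO2 (mmHg); defaults to `etco2`.
#' @param baseline_alveolar_ventilation Anchor VA (mL/min); defaults to
#'   `alveolar_ventilation`.
#' @return An object of class `gas_state`.
#' @examples
#' gas_state(40, alveolar_ventilation(20, 400, 120))
#' @export
gas_state <- function(etco2, alveolar_ventilation,
                      baseline_etco2 = etco2,
                      baseline_alveolar_ventilation = alveolar_ventilation) {
  stopifnot(etco2 > 0, alveolar_ventilation > 0, baseline_etco2 > 0,
            baseline_alveolar_ventilation > 0)
  structure(list(etco2 = etco2,
                 alveolar_ventilation = alveolar_ventilation,
                 baseline_etco2 = baseline_etco2,
                 baseline_alveolar_ventilation = baseline_alveolar_ventilation),
            class = "gas_state")
}

#' @export
print.gas_state <- function(x, ...) {
  cat(sprintf("EtCO2 %.1f mmHg at VA %.0f mL/min (anchor %.1f @ %.0f)\n",
              x$etco2, x$alveolar_ventilation, x$baseline_etco2,
              x$baseline_alveolar_ventilation))
  invisible(x)
}

#' Alveolar ventilation through a series dead space
#'
#' `VA = RR * (VT - VD)`, the Bohr series dead-space convention: the dead
#' space volume of every breath is rebreathed and does not clear CO2.
#'
#' @param rr Respiratory rate (breaths/min).
#' @param vt Tidal volume (mL).
#' @param total_dead_space Total series dead space (mL): physiologic +
#'   circuit + any device effective dead space.
#' @return Alveolar ventilation (mL/min).
#' @examples
#' alveolar_ventilation(20, 400, 120)   # 5600 mL/min
#' @export
alveolar_ventilation <- function(rr, vt, total_dead_space) {
  if (vt <= total_dead_space)
    stop("infeasible ventilation: tidal volume (", vt,
         " mL) does not exceed total dead space (", total_dead_space,
         " mL); no CO2 clearance is possible", call. = FALSE)
  rr * (vt - total_dead_space)
}

#' Steady-state EtCO2 after a change in alveolar ventilation
#'
#' Constant-inflow inverse law: `EtCO2 = baseline_etco2 *
#' baseline_VA / va_new`.
#'
#' @param va_new New alveolar ventilation (mL/min), > 0.
#' @param state A [gas_state()] carrying the baseline anchor.
#' @return Steady-state EtCO2 (mmHg).
#' @examples
#' s <- gas_state(40, 5600)
#' steady_state_etco2(2800, s)   # 80: halving VA doubles EtCO2
#' @export
steady_state_etco2 <- function(va_new, state) {
  if (va_new <= 0) stop("va_new must be > 0", call. = FALSE)
  state$baseline_etco2 * state$baseline_alveolar_ventilation / va_new
}

#' Per-breath washout toward a new steady state
#'
#' First-order relaxation of alveolar CO2 after a step change in alveolar
#' ventilation, from the explicit per-breath mass balance on a well-mixed
#' compartment of volume FRC: each breath turns over `VA/RR` of the
#' compartment, so
#' `EtCO2[n+1] = EtCO2[n] + (VA/RR/FRC) * (EtCO2_ss - EtCO2[n])`.
#' Used to honor the protocol's 2.5-min step dwell when breath-by-breath
#' dynamics are enabled; steady-state targets never depend on FRC.
#'
#' @param state A [gas_state()]; the sequence starts at `state$etco2`.
#' @param va_new New alveolar ventilation (mL/min).
#' @param frc Functional residual capacity (mL), > 0; default 2500.
#' @param rr Respiratory rate (breaths/min) during the washout.
#' @param n_breaths Number of breaths to simulate; default 50 (2.5 min at
#'   RR 20).
#' @return Numeric vector of per-breath EtCO2 values (mmHg), monotone toward
#'   the closed-form steady state.
#' @examples
#' s <- gas_state(40, 5600)
#' w <- washout_to_steady_state(s, 3758.4, frc = 2500, rr = 20)
#' utils::tail(w, 1)  # ~59.6, the closed-form target
#' @export
washout_to_steady_state <- function(state, va_new, frc = 2500, rr,
                                    n_breaths = ceiling(2.5 * rr)) {
  if (frc <= 0) stop("frc must be > 0", call. = FALSE)
  target <- steady_state_etco2(va_new, state)
  f <- min(1, (va_new / rr) / frc)
  et <- numeric(n_breaths)
  cur <- state$etco2
  for (i in seq_len(n_breaths)) {
    cur <- cur + f * (target - cur)
    et[i] <- cur
  }
  et
}
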