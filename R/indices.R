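#' Simplified mechanical power
#'
#' `MP = 0.098 * RR * VT * (Ppeak - 0.5 * driving_pressure)` in J/min, with
#' VT in LITERS. The 0.098 factor converts cmH2O * L / min to J/min. A VT
#' larger than 10 is almost certainly milliliters and raises a
#' unit-confusion error rather than returning a thousandfold power.
#'
#' @param rr Respiratory rate (breaths/min).
#' @param vt Tidal volume (L).
#' @param p_peak Peak pressure (cmH2O).
#' @param driving_pressure Driving pressure (cmH2O), <= `p_peak`.
#' @return Mechanical power (J/min).
#' @examples
#' mechanical_power(20, 0.4, 16, 6)   # 10.19 J/min
#' @export
mechanical_power <- function(rr, vt, p_peak, driving_pressure) {
  if (any(c(rr, vt, p_peak, driving_pressure) < 0))
    stop("all inputs must be >= 0", call. = FALSE)
  if (any(vt > 10))
    stop("unit confusion: vt = ", vt[which(vt > 10)[1]],
         " looks like mL; mechanical_power() expects liters", call. = FALSE)
  if (any(driving_pressure > p_peak))
    stop("driving_pressure must not exceed p_peak", call. = FALSE)
  0.098 * rr * vt * (p_peak - 0.5 * driving_pressure)
}

#' Driving pressure
#'
#' Plateau pressure minus total PEEP: the static distending pressure of the
#' breath.
#'
#' @param p_plat Plateau pressure (cmH2O).
#' @param peep_total Total PEEP (external + auto-PEEP, cmH2O).
#' @return Driving pressure (cmH2O).
#' @examples
#' driving_pressure(11, 5)   # 6
#' @export
driving_pressure <- function(p_plat, peep_total) {
  if (any(p_plat < peep_total))
    stop("p_plat must be >= peep_total", call. = FALSE)
  p_plat - peep_total
}

#' Costa index
#'
#' `4 * driving_pressure + RR` (arbitrary units), a composite predictor of
#' ventilation-induced lung injury risk.
#'
#' @param driving_pressure Driving pressure (cmH2O), >= 0.
#' @param rr Respiratory rate (breaths/min), >= 0.
#' @return Costa index (a.u.).
#' @examples
#' costa_index(6, 20)    # 44
#' costa_index(17, 20)   # 88
#' @export
costa_index <- function(driving_pressure, rr) {
  if (any(c(driving_pressure, rr) < 0))
    stop("inputs must be >= 0", call. = FALSE)
  4 * driving_pressure + rr
}

#' Sevoflurane density correction of measured tidal volume
#'
#' Flow sensors calibrated with air under-read a sevoflurane-air mixture;
#' at 1.3% expired sevoflurane the corrected volume is `measured / 0.993`.
#' Applied only to device arms, when the correction flag is set.
#'
#' @param measured_vt Measured tidal volume (mL), >= 0.
#' @return Corrected tidal volume (mL).
#' @examples
#' correct_vt_density(400)   # 402.82
#' @export
correct_vt_density <- function(measured_vt) {
  if (any(measured_vt < 0)) stop("measured_vt must be >= 0", call. = FALSE)
  measured_vt / 0.993
}

#' Percent change relative to a reference
#'
#' @param value New value.
#' @param reference Reference value, non-zero.
#' @return `100 * (value - reference) / reference` (%).
#' @examples
#' percent_change(15, 10)   # 50
#' @export
percent_change <- function(value, reference) {
  if (any(reference == 0)) stop("reference must be non-zero", call. = FALSE)
  100 * (value - reference) / reference
}
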