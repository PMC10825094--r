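#' An inhaled-sedation device arm
#'
#' A device inserted between the Y-piece and the lung adds its geometric
#' internal volume to the instrumental dead space, plus any CO2 "reflection"
#' by its conserving filter, which acts as further effective dead space. The
#' calibrated `effective_dead_space` (added mL, on top of the circuit's
#' physiologic dead space) is what the gas-exchange model uses; it is
#' expected to exceed the geometric volume, and a message flags the contrary
#' case rather than refusing it.
#'
#' @param name Device name.
#' @param geometric_volume Internal volume (mL), >= 0.
#' @param effective_dead_space Calibrated added effective dead space (mL),
#'   or `NA` before calibration.
#' @param resistance_insp,resistance_exp Added resistances (cmH2O/L/s),
#'   default 0 (pressures are measured distal to the device).
#' @param etco2_increase_pct Observed mean EtCO2 increase on insertion (%),
#'   used by [calibrate_devices()]; `NA` if unknown.
#' @param etco2_increase_sd SD of that increase (%), carried for sensitivity
#'   sweeps only.
#' @param fesevo_target Expired sevoflurane fraction metadata (default
#'   0.013).
#' @return An object of class `sedation_device`.
#' @examples
#' sedation_device("ANA-50", 50, etco2_increase_pct = 49)
#' @export
sedation_device <- function(name, geometric_volume,
                            effective_dead_space = NA_real_,
                            resistance_insp = 0, resistance_exp = 0,
                            etco2_increase_pct = NA_real_,
                            etco2_increase_sd = NA_real_,
                            fesevo_target = 0.013) {
  stopifnot(geometric_volume >= 0, resistance_insp >= 0, resistance_exp >= 0)
  if (!is.na(effective_dead_space) &&
      effective_dead_space < geometric_volume)
    message("note: ", name, " effective dead space (",
            round(effective_dead_space, 1),
            " mL) is below its geometric volume (", geometric_volume,
            " mL); CO2 reflection normally adds, not removes, dead space")
  structure(list(name = name, geometric_volume = geometric_volume,
                 effective_dead_space = effective_dead_space,
                 resistance_insp = resistance_insp,
                 resistance_exp = resistance_exp,
                 etco2_increase_pct = etco2_increase_pct,
                 etco2_increase_sd = etco2_increase_sd,
                 fesevo_target = fesevo_target),
            class = "sedation_device")
}

#' @export
print.sedation_device <- function(x, ...) {
  cat(sprintf("%s: geometric %g mL, effective added dead space %s mL\n",
              x$name, x$geometric_volume,
              if (is.na(x$effective_dead_space)) "(uncalibrated)"
              else sprintf("%.1f", x$effective_dead_space)))
  invisible(x)
}

#' Shipped device catalog
#'
#' Reads the packaged device table (name, geometric volume, observed mean
#' EtCO2 increase and its SD) and returns a list of [sedation_device()]
#' objects, uncalibrated. The shipped defaults transcribe the three ICU
#' devices: AnaConDa-50, AnaConDa-100 and MIRUS.
#'
#' @param path Path to a device CSV; defaults to the packaged catalog.
#' @return Named list of `sedation_device` objects.
#' @examples
#' names(device_catalog())
#' @export
device_catalog <- function(path = system.file("extdata", "devices.csv",
                                              package = "ventbench")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(d)), function(i)
    sedation_device(d$name[i], d$geometric_volume_mL[i],
                    resistance_insp = d$resistance_insp[i],
                    resistance_exp = d$resistance_exp[i],
                    etco2_increase_pct = d$etco2_increase_pct[i],
                    etco2_increase_sd = d$etco2_increase_sd_pct[i]))
  names(out) <- d$name
  out
}
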