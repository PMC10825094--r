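#' Total effective dead space implied by an EtCO2 ratio
#'
#' Inverts the constant-inflow steady-state law. If inserting a device
#' multiplies EtCO2 by `ratio` at unchanged VT and RR, then alveolar
#' ventilation fell by the same factor, so the total series dead space is
#' `VD_total = VT - (VT - VD_phys) / ratio`.
#'
#' @param ratio EtCO2 ratio device/baseline (dimensionless, >= 1).
#' @param vt Tidal volume (mL) at which the ratio was observed.
#' @param rr Respiratory rate (breaths/min); enters only via the round-trip
#'   (the closed form is RR-free), kept in the signature for symmetry with
#'   the forward model.
#' @param physiologic_dead_space Circuit + physiologic dead space (mL).
#' @return Total effective dead space (mL).
#' @examples
#' effective_dead_space_from_ratio(1.49, 400, 20, 120)  # 212.08 mL total
#' @export
effective_dead_space_from_ratio <- function(ratio, vt, rr,
                                            physiologic_dead_space) {
  if (ratio < 1)
    stop("out of domain: ratio < 1 (a device cannot reduce dead space)",
         call. = FALSE)
  if (vt <= physiologic_dead_space)
    stop("vt must exceed physiologic_dead_space", call. = FALSE)
  vt - (vt - physiologic_dead_space) / ratio
}

#' Calibrate device effective dead spaces from observed EtCO2 increases
#'
#' For each device, converts its observed mean percent EtCO2 increase into a
#' constant effective dead space via [effective_dead_space_from_ratio()],
#' under the stated baseline (40 mmHg at VT 400 mL, RR 20/min, 120 mL
#' circuit dead space by default). The calibrated added dead space is the
#' total minus the circuit value; its excess over the geometric volume
#' quantifies CO2 reflection by the conserving filter.
#'
#' @param devices List of [sedation_device()] objects (default: the shipped
#'   catalog) with `etco2_increase_pct` set.
#' @param vt,rr Baseline settings the increases were observed at.
#' @param physiologic_dead_space Circuit dead space at calibration (mL).
#' @return Object of class `device_calibration`: the input list with
#'   `effective_dead_space` filled in, plus a `summary` data frame (device,
#'   geometric volume, total and added effective dead space, reflection
#'   excess).
#' @examples
#' cal <- calibrate_devices()
#' cal$summary
#' @export
calibrate_devices <- function(devices = device_catalog(), vt = 400, rr = 20,
                              physiologic_dead_space = 120) {
  out <- lapply(devices, function(d) {
    ratio <- 1 + d$etco2_increase_pct / 100
    total <- effective_dead_space_from_ratio(ratio, vt, rr,
                                             physiologic_dead_space)
    d$effective_dead_space <- total - physiologic_dead_space
    d
  })
  summ <- data.frame(
    device = vapply(out, `[[`, "", "name"),
    geometric_volume_mL = vapply(out, `[[`, 0, "geometric_volume"),
    added_dead_space_mL = vapply(out, `[[`, 0, "effective_dead_space"),
    row.names = NULL)
  summ$total_dead_space_mL <- summ$added_dead_space_mL +
    physiologic_dead_space
  summ$reflection_excess_mL <- summ$added_dead_space_mL -
    summ$geometric_volume_mL
  structure(list(devices = out, summary = summ, vt = vt, rr = rr,
                 physiologic_dead_space = physiologic_dead_space),
            class = "device_calibration")
}

#' @export
print.device_calibration <- function(x, ...) {
  cat(sprintf(
    "Device dead-space calibration (VT %g mL, RR %g/min, circuit VD %g mL)\n",
    x$vt, x$rr, x$physiologic_dead_space))
  print(format(x$summary, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
coef.device_calibration <- function(object, ...) {
  stats::setNames(object$summary$added_dead_space_mL, object$summary$device)
}

#' Brute-force feasible dead-space interval for observed titration endpoints
#'
#' Scans candidate added dead-space values on a fine grid and keeps those
#' for which the titration controller reproduces every supplied endpoint
#' (final VT for the VT arm, final RR for the RR arm). An empty interval is
#' a model-inconsistency finding, returned (not raised): no single constant
#' dead space can explain both endpoints.
#'
#' Endpoints that do not lie on the titration grid (baseline + k steps) are
#' excluded with a warning rather than snapped to a neighbor.
#'
#' @param final_vt,final_rr Observed endpoints (mL, breaths/min); `NULL` to
#'   leave that arm unconstrained.
#' @param base Baseline [vent_settings()].
#' @param lung [lung_circuit()] providing the physiologic dead space.
#' @param target,band EtCO2 target and half-band (mmHg), default 40 +/- 2.
#' @param step_vt,step_rr Titration increments, default 60 mL and
#'   3 breaths/min (15% of baseline).
#' @param resolution Scan resolution (mL), default 0.1.
#' @return Numeric vector `c(lower, upper)` of TOTAL effective dead space
#'   (mL, circuit + device), or a zero-length numeric with attribute
#'   `empty = TRUE` when no candidate reproduces all endpoints. With no
#'   endpoints, the full scan range `[circuit dead space, VT)`.
#' @examples
#' feasible_dead_space_interval(final_vt = 520, final_rr = 29,
#'                              base = vent_settings(),
#'                              lung = lung_circuit(40))
#' @export
feasible_dead_space_interval <- function(final_vt = NULL, final_rr = NULL,
                                         base = vent_settings(),
                                         lung = lung_circuit(40),
                                         target = 40, band = 2,
                                         step_vt = 60, step_rr = 3,
                                         resolution = 0.1) {
  on_grid <- function(x, base0, step) {
    k <- (x - base0) / step
    abs(k - round(k)) < 1e-9 && k > -1e-9
  }
  if (!is.null(final_vt) && !on_grid(final_vt, base$tidal_volume, step_vt)) {
    warning("final_vt ", final_vt, " is not on the titration grid (",
            base$tidal_volume, " + k*", step_vt,
            "); endpoint excluded from the scan", call. = FALSE)
    final_vt <- NULL
  }
  if (!is.null(final_rr) && !on_grid(final_rr, base$rate, step_rr)) {
    warning("final_rr ", final_rr, " is not on the titration grid (",
            base$rate, " + k*", step_rr,
            "); endpoint excluded from the scan", call. = FALSE)
    final_rr <- NULL
  }

  vd0 <- lung$dead_space
  cand <- seq(vd0, base$tidal_volume - resolution, by = resolution)
  if (is.null(final_vt) && is.null(final_rr))
    return(range(cand))

  base_va <- base$rate * (base$tidal_volume - vd0)
  need <- target * base_va / (target + band)   # VA needed at the stop rule
  ok <- rep(TRUE, length(cand))
  # closed-form first-crossing endpoints over the candidate dead spaces:
  # EtCO2(setting) = target * base_va / VA(setting); stop at the first grid
  # value with EtCO2 <= target + band
  if (!is.null(final_vt)) {
    vt_final <- cand + need / base$rate
    k <- ceiling((vt_final - base$tidal_volume) / step_vt - 1e-9)
    k[k < 0] <- 0
    ok <- ok & (base$tidal_volume + k * step_vt == final_vt)
  }
  if (!is.null(final_rr)) {
    rr_final <- need / (base$tidal_volume - cand)
    k <- ceiling((rr_final - base$rate) / step_rr - 1e-9)
    k[k < 0] <- 0
    ok <- ok & (base$rate + k * step_rr == final_rr)
  }
  if (!any(ok))
    return(structure(numeric(0), empty = TRUE))
  range(cand[ok])
}
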