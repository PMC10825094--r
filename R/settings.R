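#' Ventilator settings for volume-controlled ventilation
#'
#' Bundles the controlled knobs of a volume-controlled breath with a square
#' inspiratory flow and an end-inspiratory pause. All validation happens here
#' so downstream mechanics and gas-exchange code can assume a feasible breath.
#'
#' @param tidal_volume Set tidal volume (mL), >= 0.
#' @param flow Inspiratory flow (L/min), > 0. Square (constant) profile.
#' @param pause End-inspiratory pause (s), >= 0.
#' @param rate Respiratory rate (breaths/min), > 0.
#' @param peep Set external PEEP (cmH2O), >= 0.
#' @param fio2 Inspired oxygen fraction, metadata only (default 0.21).
#'
#' @return An object of class `vent_settings`.
#' @examples
#' vent_settings()                      # protocol defaults: 400/60/0.4/20/5
#' vent_settings(rate = 35, peep = 15)
#' @export
vent_settings <- function(tidal_volume = 400, flow = 60, pause = 0.4,
                          rate = 20, peep = 5, fio2 = 0.21) {
  stopifnot(is.numeric(tidal_volume), is.numeric(flow), is.numeric(pause),
            is.numeric(rate), is.numeric(peep))
  if (tidal_volume < 0) stop("tidal_volume must be >= 0", call. = FALSE)
  if (flow <= 0) stop("flow must be > 0", call. = FALSE)
  if (pause < 0) stop("pause must be >= 0", call. = FALSE)
  if (rate <= 0) stop("rate must be > 0", call. = FALSE)
  if (peep < 0) stop("peep must be >= 0", call. = FALSE)
  x <- structure(list(tidal_volume = tidal_volume, flow = flow, pause = pause,
                      rate = rate, peep = peep, fio2 = fio2),
                 class = "vent_settings")
  # inspiratory time must leave room to exhale
  bt <- breath_timing(x)
  if (bt[["t_exp"]] <= 0)
    stop("invalid settings: inspiratory time ", signif(bt[["t_insp"]], 4),
         " s leaves no expiratory time at rate ", rate, "/min", call. = FALSE)
  x
}

#' @export
print.vent_settings <- function(x, ...) {
  bt <- breath_timing(x)
  cat("Volume-controlled ventilation settings\n")
  cat(sprintf("  VT %g mL | flow %g L/min | pause %g s | RR %g /min | PEEP %g cmH2O\n",
              x$tidal_volume, x$flow, x$pause, x$rate, x$peep))
  cat(sprintf("  Ti %.3f s, Te %.3f s (cycle %.3f s)\n",
              bt[["t_insp"]], bt[["t_exp"]], 60 / x$rate))
  invisible(x)
}

#' Inspiratory and expiratory times of a breath
#'
#' Ti = VT/flow + pause (square flow); Te = 60/RR - Ti.
#'
#' @param settings A [vent_settings()] object (or a bare list with the same
#'   fields; used internally before full validation).
#' @return Named numeric vector `c(t_insp = , t_exp = )` in seconds.
#' @examples
#' breath_timing(vent_settings())  # 0.8 s, 2.2 s
#' @export
breath_timing <- function(settings) {
  t_insp <- settings$tidal_volume / 1000 / lpm_to_lps(settings$flow) +
    settings$pause
  t_exp <- 60 / settings$rate - t_insp
  c(t_insp = t_insp, t_exp = t_exp)
}

# flow unit conversion is centralized here: settings carry L/min, all
# resistive-pressure arithmetic uses L/s
lpm_to_lps <- function(flow_lpm) flow_lpm / 60
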