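#' Passive single-compartment lung and circuit
#'
#' A linear one-compartment respiratory system: constant compliance, fixed
#' (possibly direction-dependent) resistance, and a series dead space between
#' the Y-piece and the compartment.
#'
#' @param compliance Compliance (mL/cmH2O), > 0.
#' @param resistance_insp Inspiratory resistance (cmH2O/L/s), >= 0.
#' @param resistance_exp Expiratory resistance (cmH2O/L/s); defaults to
#'   `resistance_insp`.
#' @param dead_space Physiologic + circuit dead space (mL), >= 0.
#' @param label Free-text label.
#'
#' @return An object of class `lung_circuit`.
#' @examples
#' lung_circuit(compliance = 60)        # dry-bench defaults: R 5, VD 120
#' lung_btps()                          # humidified rig: C 25, R 15, VD 150
#' @export
lung_circuit <- function(compliance, resistance_insp = 5,
                         resistance_exp = resistance_insp,
                         dead_space = 120, label = "ATPD test lung") {
  stopifnot(is.numeric(compliance), is.numeric(resistance_insp),
            is.numeric(resistance_exp), is.numeric(dead_space))
  if (compliance <= 0) stop("compliance must be > 0", call. = FALSE)
  if (resistance_insp < 0 || resistance_exp < 0)
    stop("resistances must be >= 0", call. = FALSE)
  if (dead_space < 0) stop("dead_space must be >= 0", call. = FALSE)
  structure(list(compliance = compliance,
                 resistance_insp = resistance_insp,
                 resistance_exp = resistance_exp,
                 dead_space = dead_space, label = label),
            class = "lung_circuit")
}

#' @rdname lung_circuit
#' @export
lung_btps <- function(compliance = 25, resistance_insp = 15,
                      resistance_exp = resistance_insp, dead_space = 150) {
  lung_circuit(compliance, resistance_insp, resistance_exp, dead_space,
               label = "BTPS test lung")
}

#' @export
print.lung_circuit <- function(x, ...) {
  cat(sprintf("%s: C %g mL/cmH2O, R %g/%g cmH2O/L/s (insp/exp), VD %g mL\n",
              x$label, x$compliance, x$resistance_insp, x$resistance_exp,
              x$dead_space))
  invisible(x)
}
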