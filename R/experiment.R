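#' Configuration of a factorial bench run
#'
#' Defines the experimental grid: scenario (dry ATPD rig or humidified BTPS
#' rig), compliances, PEEP levels, device arms, baseline ventilator
#' settings, circuit dead space, EtCO2 target band and behavioral flags.
#' ATPD defaults: compliances 20/40/60 mL/cmH2O, PEEP 5/15 cmH2O,
#' resistance 5 cmH2O/L/s, 120 mL circuit dead space. BTPS defaults: single
#' compliance 25 mL/cmH2O, resistance 15, 150 mL dead space.
#'
#' Device calibration always uses the dry-condition EtCO2 increases under
#' the dry baseline (VT 400, RR 20, VD 120): per-device humid-condition
#' increases are not available, so BTPS runs reuse the dry effective dead
#' spaces (a documented limitation).
#'
#' @param scenario `"ATPD"` or `"BTPS"`.
#' @param compliances Compliances (mL/cmH2O); scenario default if `NULL`.
#' @param peeps PEEP levels (cmH2O).
#' @param devices List of calibrated [sedation_device()]s; default: shipped
#'   catalog calibrated with [calibrate_devices()].
#' @param base Baseline [vent_settings()] (PEEP field is overridden per grid
#'   cell).
#' @param resistance,dead_space Lung/circuit parameters (scenario default if
#'   `NULL`).
#' @param target,band EtCO2 target and half-band (mmHg).
#' @param density_correction Logical: also report device-arm tidal volumes
#'   and mechanical power corrected for sevoflurane density (/0.993).
#' @param dynamics Logical: titrate on end-of-dwell washout values instead
#'   of closed-form steady states.
#' @param ctrl_states `"full"` (CTRL carries no-op corrected states, full
#'   factorial) or `"baseline_only"`.
#' @return Object of class `experiment_config`.
#' @examples
#' experiment_config()
#' experiment_config("BTPS")
#' @export
experiment_config <- function(scenario = c("ATPD", "BTPS"),
                              compliances = NULL, peeps = c(5, 15),
                              devices = NULL, base = vent_settings(),
                              resistance = NULL, dead_space = NULL,
                              target = 40, band = 2,
                              density_correction = TRUE, dynamics = FALSE,
                              ctrl_states = c("full", "baseline_only")) {
  scenario <- match.arg(scenario)
  ctrl_states <- match.arg(ctrl_states)
  if (is.null(compliances))
    compliances <- if (scenario == "ATPD") c(20, 40, 60) else 25
  if (is.null(resistance)) resistance <- if (scenario == "ATPD") 5 else 15
  if (is.null(dead_space)) dead_space <- if (scenario == "ATPD") 120 else 150
  if (is.null(devices)) devices <- calibrate_devices()$devices
  structure(list(scenario = scenario, compliances = compliances,
                 peeps = peeps, devices = devices, base = base,
                 resistance = resistance, dead_space = dead_space,
                 target = target, band = band,
                 density_correction = density_correction,
                 dynamics = dynamics, ctrl_states = ctrl_states),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("%s bench config: C {%s} mL/cmH2O, PEEP {%s} cmH2O, R %g, VD %g mL\n",
              x$scenario, paste(x$compliances, collapse = ", "),
              paste(x$peeps, collapse = ", "), x$resistance, x$dead_space))
  cat(sprintf("  arms: CTRL + %s; EtCO2 target %g +/- %g mmHg\n",
              paste(vapply(x$devices, `[[`, "", "name"), collapse = ", "),
              x$target, x$band))
  invisible(x)
}

#' Read an experiment configuration from a YAML file
#'
#' Accepts the scalar fields of [experiment_config()] (scenario,
#' compliances, peeps, resistance, dead_space, target, band,
#' density_correction, dynamics, ctrl_states) plus optional `base` settings
#' (tidal_volume, flow, pause, rate, peep).
#'
#' @param path Path to a YAML config file.
#' @return Object of class `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- if (is.null(y$base)) vent_settings() else do.call(vent_settings, y$base)
  args <- y[setdiff(names(y), "base")]
  args$base <- base
  args$compliances <- if (is.null(y$compliances)) NULL else unlist(y$compliances)
  args$peeps <- if (is.null(y$peeps)) c(5, 15) else unlist(y$peeps)
  do.call(experiment_config, args)
}

#' Run the factorial bench experiment
#'
#' For every compliance x PEEP condition: the no-device CTRL arm anchors
#' EtCO2 at the target; each device arm then gets a with-device baseline
#' (EtCO2 rise at unchanged settings) and both titration arms (VT
#' correction, RR correction), with breath mechanics re-simulated at the
#' final settings and derived indices computed on unrounded values.
#' Per-row failures are recorded in the `error` column, never fatal to the
#' grid. Deterministic given the configuration.
#'
#' @param config An [experiment_config()].
#' @return Object of class `bench_grid`: a data frame with one row per
#'   (condition x arm x state), columns for settings, pressures, EtCO2,
#'   titration outcome and indices (`mp` and, when enabled,
#'   `mp_density_corrected` with `vt_corrected`), plus `pct_mp_vs_ctrl`,
#'   the percent change of mechanical power against the same-condition CTRL
#'   baseline.
#' @examples
#' g <- run_grid(experiment_config(compliances = 40, peeps = 5))
#' subset(g, arm == "ANA-50", c(state, final_vt, final_rr, etco2, mp))
#' @export
run_grid <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- list()
  states_dev <- c("baseline", "vt_corrected", "rr_corrected")
  states_ctrl <- if (config$ctrl_states == "full") states_dev else "baseline"

  for (C in config$compliances) for (peep in config$peeps) {
    lung <- lung_circuit(C, config$resistance,
                         dead_space = config$dead_space,
                         label = config$scenario)
    base <- vent_settings(config$base$tidal_volume, config$base$flow,
                          config$base$pause, config$base$rate, peep,
                          config$base$fio2)
    cond <- sprintf("%s_C%g_PEEP%g", config$scenario, C, peep)

    ctrl_mech <- simulate_breath(base, lung)
    ctrl_row <- index_row(config, cond, C, peep, "CTRL", "baseline",
                          base, ctrl_mech, config$target, n_steps = 0,
                          within_band = TRUE, device_arm = FALSE)
    ctrl_mp <- ctrl_row$mp
    for (st in states_ctrl) {
      r <- ctrl_row; r$state <- st
      r$pct_mp_vs_ctrl <- 0
      rows[[length(rows) + 1]] <- r
    }

    for (dev in config$devices) {
      res <- tryCatch({
        vd_total <- lung$dead_space + dev$effective_dead_space
        base_va <- alveolar_ventilation(base$rate, base$tidal_volume,
                                        lung$dead_space)
        anchor <- gas_state(config$target, base_va)
        et_dev <- steady_state_etco2(
          alveolar_ventilation(base$rate, base$tidal_volume, vd_total),
          anchor)
        dev_mech <- simulate_breath(base, lung, dev$resistance_insp,
                                    dev$resistance_exp)
        out <- list()
        r <- index_row(config, cond, C, peep, dev$name, "baseline",
                       base, dev_mech, et_dev, n_steps = 0,
                       within_band = FALSE, device_arm = TRUE)
        r$pct_mp_vs_ctrl <- percent_change(r$mp, ctrl_mp)
        out[[1]] <- r
        for (mode in c("VT", "RR")) {
          tr <- titrate(mode, dev, base, lung, config$target, config$band,
                        dynamics = config$dynamics)
          st <- if (mode == "VT") "vt_corrected" else "rr_corrected"
          r <- index_row(config, cond, C, peep, dev$name, st,
                         tr$final_settings, tr$mechanics, tr$final_etco2,
                         n_steps = tr$n_steps, within_band = tr$within_band,
                         device_arm = TRUE)
          r$pct_mp_vs_ctrl <- percent_change(r$mp, ctrl_mp)
          out[[length(out) + 1]] <- r
        }
        out
      }, error = function(e) {
        lapply(states_dev, function(st) {
          r <- empty_row(config, cond, C, peep, dev$name, st)
          r$error <- conditionMessage(e)
          r
        })
      })
      rows <- c(rows, res)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("bench_grid", "data.frame")
  out
}

# one assembled result row; indices on unrounded model values
index_row <- function(config, cond, C, peep, arm, state, settings, mech,
                      etco2, n_steps, within_band, device_arm) {
  dp <- driving_pressure(mech$p_plat, mech$peep_total)
  vt_l <- settings$tidal_volume / 1000
  mp <- mechanical_power(settings$rate, vt_l, mech$p_peak, dp)
  vt_corr <- if (device_arm && config$density_correction)
    correct_vt_density(settings$tidal_volume) else settings$tidal_volume
  mp_corr <- mechanical_power(settings$rate, vt_corr / 1000, mech$p_peak, dp)
  data.frame(scenario = config$scenario, condition = cond, compliance = C,
             peep = peep, arm = arm, state = state,
             final_vt = settings$tidal_volume, final_rr = settings$rate,
             p_peak = mech$p_peak, p_plat = mech$p_plat,
             peep_total = mech$peep_total, auto_peep = mech$auto_peep,
             etco2 = etco2, dp = dp, costa = costa_index(dp, settings$rate),
             mp = mp, vt_density_corrected = vt_corr,
             mp_density_corrected = mp_corr, n_steps = n_steps,
             within_band = within_band, pct_mp_vs_ctrl = NA_real_,
             error = NA_character_, stringsAsFactors = FALSE)
}

empty_row <- function(config, cond, C, peep, arm, state) {
  data.frame(scenario = config$scenario, condition = cond, compliance = C,
             peep = peep, arm = arm, state = state, final_vt = NA_real_,
             final_rr = NA_real_, p_peak = NA_real_, p_plat = NA_real_,
             peep_total = NA_real_, auto_peep = NA_real_, etco2 = NA_real_,
             dp = NA_real_, costa = NA_real_, mp = NA_real_,
             vt_density_corrected = NA_real_,
             mp_density_corrected = NA_real_, n_steps = NA_integer_,
             within_band = NA, pct_mp_vs_ctrl = NA_real_,
             error = NA_character_, stringsAsFactors = FALSE)
}

#' @export
print.bench_grid <- function(x, ...) {
  cat(sprintf("Bench grid: %d rows (%s; %d condition(s) x %d arm(s))\n",
              nrow(x), x$scenario[1],
              length(unique(x$condition)), length(unique(x$arm))))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, 2)
  print(df[c("condition", "arm", "state", "final_vt", "final_rr",
             "etco2", "p_peak", "p_plat", "peep_total", "dp", "costa",
             "mp")], ...)
  invisible(x)
}

#' @export
summary.bench_grid <- function(object, ...) {
  df <- as.data.frame(object)
  dev <- df[df$arm != "CTRL" & df$state != "baseline", ]
  cat("Mechanical power increase vs CTRL baseline, corrected states (%):\n")
  print(round(tapply(dev$pct_mp_vs_ctrl, list(dev$arm, dev$state), mean), 1))
  invisible(object)
}

#' Packaged reference table of bench measurements
#'
#' Transcription of the reference bench results (pressures, driving
#' pressure, Costa index and final settings per condition, arm and state)
#' with a provenance note column; cells flagged in `note` (e.g. a final
#' tidal volume off the titration grid) are excluded from grid comparisons.
#'
#' @return Data frame keyed by (compliance, peep, arm, state).
#' @export
table1_reference <- function() {
  utils::read.csv(system.file("extdata", "table1_reference.csv",
                              package = "ventbench"),
                  stringsAsFactors = FALSE)
}

#' Compare simulated grid results against the reference table
#'
#' Per-cell absolute deviations for Ppeak, Pplat, PEEPt, driving pressure,
#' Costa index and final settings, with tolerance flags (1 cmH2O for
#' pressures, 2 a.u. for the Costa index, exact for final VT/RR).
#' Mismatches are reported, never raised: the idealized one-compartment
#' model is expected to miss some measured cells (notably the C = 20
#' baseline driving pressure) and the report is the instrument for saying
#' so.
#'
#' @param results A `bench_grid` from [run_grid()].
#' @param reference Reference data frame, default [table1_reference()].
#' @return Object of class `deviation_report`: merged data frame with
#'   `dev_*` columns and `ok_*` flags, plus a `summary` table of cells
#'   within tolerance.
#' @export
compare_to_reference <- function(results, reference = table1_reference()) {
  keys <- c("compliance", "peep", "arm", "state")
  if (!all(keys %in% names(results)) || !all(keys %in% names(reference)))
    stop("structural error: results and reference must both carry keys ",
         paste(keys, collapse = ", "), call. = FALSE)
  ref <- reference
  ref$note[is.na(ref$note)] <- ""
  m <- merge(as.data.frame(results), ref, by = keys,
             suffixes = c("", "_ref"))
  if (nrow(m) == 0)
    stop("structural error: no reference rows match the result keys",
         call. = FALSE)
  excl <- m$note != ""
  tolerances <- c(p_peak = 1, p_plat = 1, peep_total = 1, dp = 1,
                  costa = 2, final_vt = 0, final_rr = 0)
  for (v in names(tolerances)) {
    rv <- m[[paste0(v, "_ref")]]
    d <- abs(m[[v]] - rv)
    d[excl] <- NA
    m[[paste0("dev_", v)]] <- d
    m[[paste0("ok_", v)]] <- d <= tolerances[[v]]
  }
  summ <- data.frame(
    variable = names(tolerances),
    tolerance = unname(tolerances),
    n_compared = vapply(names(tolerances), function(v)
      sum(!is.na(m[[paste0("dev_", v)]])), 0L),
    n_within = vapply(names(tolerances), function(v)
      sum(m[[paste0("ok_", v)]], na.rm = TRUE), 0L),
    max_deviation = vapply(names(tolerances), function(v)
      if (all(is.na(m[[paste0("dev_", v)]]))) NA_real_
      else max(m[[paste0("dev_", v)]], na.rm = TRUE), 0),
    row.names = NULL)
  structure(list(cells = m, summary = summ), class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat("Deviation report: simulated grid vs reference table\n")
  print(x$summary, row.names = FALSE)
  out <- x$cells
  bad <- out[!is.na(out$dev_dp) & !out$ok_dp, c("compliance", "peep", "arm",
                                                "state", "dp", "dp_ref",
                                                "dev_dp")]
  if (nrow(bad)) {
    cat("Driving-pressure cells out of tolerance:\n")
    print(bad, row.names = FALSE)
  }
  invisible(x)
}

#' Write grid results as tidy CSV plus a JSON summary
#'
#' @param results A `bench_grid`.
#' @param dir Output directory (created if missing).
#' @param calibration Optional [calibrate_devices()] result to include.
#' @param report Optional [compare_to_reference()] result to include.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, dir, calibration = NULL, report = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "results.csv")
  utils::write.csv(as.data.frame(results), csv, row.names = FALSE)
  summ <- list(n_rows = nrow(results),
               scenario = unique(results$scenario))
  if (!is.null(calibration)) summ$calibration <- calibration$summary
  if (!is.null(report)) summ$deviations <- report$summary
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(csv = csv, json = js))
}
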