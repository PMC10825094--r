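#' Generate synthetic bench records
#'
#' Stand-in for the physical rig: runs the deterministic simulator over the
#' configured grid, then emulates the bench's measurement process — optional
#' zero-mean Gaussian noise on pressures and EtCO2, followed by the
#' measurement rounding conventions (pressures to whole cmH2O, EtCO2 to
#' 0.1 mmHg, volumes to 1 mL). Noise is purely an instrument for exercising
#' pipeline robustness: the real bench is reported as deterministic within
#' condition, so the noise-free records are the reference behavior.
#'
#' Reproducibility contract: the same `seed` yields bit-identical records;
#' zero noise SDs reproduce the ideal model exactly after rounding. The
#' caller's RNG state is left untouched.
#'
#' @param config An [experiment_config()]; the default full ATPD factorial
#'   (3 compliances x 2 PEEPs x 4 arms x 3 states, CTRL corrections as
#'   no-ops) yields 72 records per replicate.
#' @param noise_sd_pressure SD of pressure noise (cmH2O), default 0.
#' @param noise_sd_etco2 SD of EtCO2 noise (mmHg), default 0.
#' @param seed Integer seed for the noise draws.
#' @param replicates Number of noisy replicates of the deterministic grid
#'   (the simulator runs once; noise is redrawn per replicate).
#' @return Data frame of class `bench_records`: grid keys, measured
#'   (rounded) `p_peak`, `p_plat`, `peep_total`, `etco2`, set `final_vt` and
#'   `final_rr`, plus `seed` and `replicate` provenance columns.
#' @examples
#' r <- generate_bench_records(noise_sd_etco2 = 1, seed = 7)
#' nrow(r)  # 72
#' @export
generate_bench_records <- function(config = experiment_config(),
                                   noise_sd_pressure = 0,
                                   noise_sd_etco2 = 0, seed = 1,
                                   replicates = 1) {
  grid <- as.data.frame(run_grid(config))
  keep <- c("scenario", "condition", "compliance", "peep", "arm", "state",
            "p_peak", "p_plat", "peep_total", "etco2", "final_vt",
            "final_rr")
  grid <- grid[keep]

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  reps <- lapply(seq_len(replicates), function(rep) {
    g <- grid
    n <- nrow(g)
    for (v in c("p_peak", "p_plat", "peep_total"))
      g[[v]] <- round(g[[v]] + stats::rnorm(n, 0, noise_sd_pressure))
    g$etco2 <- round(g$etco2 + stats::rnorm(n, 0, noise_sd_etco2), 1)
    g$final_vt <- round(g$final_vt)
    g$final_rr <- round(g$final_rr)
    g$seed <- seed
    g$replicate <- rep
    g
  })
  out <- do.call(rbind, reps)
  rownames(out) <- NULL
  class(out) <- c("bench_records", "data.frame")
  out
}
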