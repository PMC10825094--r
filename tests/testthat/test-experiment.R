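test_that("the default dry-rig factorial has the expected structure", {
  g <- run_grid(experiment_config())
  expect_s3_class(g, "bench_grid")
  expect_equal(nrow(g), 72)   # 3 C x 2 PEEP x 4 arms x 3 states
  expect_true(all(is.na(g$error)))
  dev <- g[g$arm != "CTRL", ]
  expect_equal(as.integer(table(dev$state)),
               rep(18L, 3))  # each device arm carries both titration modes
})

test_that("a control-only grid shows zero percent change everywhere", {
  g <- run_grid(experiment_config(compliances = 60, peeps = 5,
                                  devices = list()))
  expect_true(all(g$arm == "CTRL"))
  expect_true(all(g$pct_mp_vs_ctrl == 0))
})

test_that("the humidified scenario runs a single-compliance grid at both PEEPs", {
  g <- run_grid(experiment_config("BTPS"))
  expect_equal(unique(g$compliance), 25)
  expect_equal(sort(unique(g$peep)), c(5, 15))
  expect_equal(nrow(g), 24)
  # stiffer circuit resistance shows up in the peak-plateau gap
  ctrl <- g[g$arm == "CTRL" & g$state == "baseline" & g$peep == 5, ]
  expect_equal(ctrl$p_peak - ctrl$p_plat, 15 * 1)
})

test_that("two runs of the same config produce byte-identical CSV output", {
  cfg <- experiment_config(compliances = c(20, 60), peeps = 5)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(run_grid(cfg)), f1, row.names = FALSE)
  write.csv(as.data.frame(run_grid(cfg)), f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the four self-consistent titration endpoints match the reference exactly", {
  g <- as.data.frame(run_grid(experiment_config()))
  pick <- function(arm, state, col) {
    v <- unique(g[g$arm == arm & g$state == state, col])
    expect_length(v, 1)   # identical across all conditions
    v
  }
  expect_equal(pick("ANA-100", "vt_corrected", "final_vt"), 580)
  expect_equal(pick("ANA-50", "vt_corrected", "final_vt"), 520)
  expect_equal(pick("MIRUS", "rr_corrected", "final_rr"), 35)
  expect_equal(pick("ANA-50", "rr_corrected", "final_rr"), 29)
})

test_that("corrected mechanical power exceeds control in every condition, ANA-50 least", {
  g <- as.data.frame(run_grid(experiment_config()))
  for (cond in unique(g$condition)) {
    cc <- g[g$condition == cond, ]
    ctrl_mp <- cc$mp[cc$arm == "CTRL" & cc$state == "baseline"]
    dev <- cc[cc$arm != "CTRL" & cc$state != "baseline", ]
    expect_true(all(dev$mp > ctrl_mp), info = cond)
    for (st in c("vt_corrected", "rr_corrected")) {
      inc <- dev[dev$state == st, ]
      expect_equal(inc$arm[which.min(inc$pct_mp_vs_ctrl)], "ANA-50",
                   info = paste(cond, st))
    }
  }
})

test_that("the deviation report flags the stiff-lung baseline driving pressure", {
  g <- run_grid(experiment_config())
  rep <- compare_to_reference(g)
  cells <- rep$cells
  # ideal model: dP = 400/20 = 20 vs measured 17 at C = 20 baseline
  bad <- cells[cells$compliance == 20 & cells$state == "baseline" &
                 cells$arm == "CTRL" & cells$peep == 5, ]
  expect_equal(bad$dev_dp, 3, tolerance = 0.01)
  expect_false(bad$ok_dp)
  # compliant-lung control baseline is within a cmH2O everywhere
  good <- cells[cells$compliance == 60 & cells$state == "baseline" &
                  cells$arm == "CTRL", ]
  expect_true(all(good$ok_p_peak & good$ok_p_plat & good$ok_peep_total))
})

test_that("the reference compared against itself deviates nowhere", {
  ref <- table1_reference()
  rep <- compare_to_reference(ref, ref)
  dev_cols <- grep("^dev_", names(rep$cells), value = TRUE)
  for (v in dev_cols)
    expect_true(all(rep$cells[[v]] == 0, na.rm = TRUE))
  expect_error(compare_to_reference(data.frame(x = 1), ref),
               "structural error")
})

test_that("YAML configs round-trip into experiment configurations", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("scenario: BTPS", "peeps: [5, 15]", "target: 40", "band: 2",
               "base:", "  tidal_volume: 400", "  rate: 20"), f)
  cfg <- read_experiment_config(f)
  expect_equal(cfg$scenario, "BTPS")
  expect_equal(cfg$compliances, 25)
  expect_equal(cfg$dead_space, 150)
  expect_equal(cfg$base$tidal_volume, 400)
})

test_that("results export writes tidy CSV plus a JSON summary", {
  dir <- withr::local_tempdir()
  g <- run_grid(experiment_config(compliances = 40, peeps = 5))
  paths <- write_results(g, dir, calibration = calibrate_devices(),
                         report = compare_to_reference(g))
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths[["csv"]])
  expect_equal(nrow(back), nrow(g))
  js <- jsonlite::read_json(paths[["json"]])
  expect_equal(js$n_rows, nrow(g))
  expect_length(js$calibration, 3)
})
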