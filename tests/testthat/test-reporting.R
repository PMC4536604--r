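test_that("duplicate-pair CSVs round-trip and collect rejects with line numbers", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "pairs.csv")
  cfg <- simulation_config(labs = lab_profile("L1", analytical_cv = 0.03),
                           n_days = 30, seed = 2)
  dup <- simulate_duplicate_stream(cfg)
  write_qc_csv(dup, path)
  back <- read_duplicate_csv(path)
  expect_equal(nrow(back$rejects), 0)
  expect_equal(as.data.frame(back$records), as.data.frame(dup))

  # header-only file: zero records, zero rejects
  writeLines("lab_id,instrument,date,level,day1_count,day2_count",
             file.path(dir, "empty.csv"))
  empty <- read_duplicate_csv(file.path(dir, "empty.csv"))
  expect_equal(nrow(empty$records), 0)
  expect_equal(nrow(empty$rejects), 0)

  # bad rows are soft rejects with their line numbers and reasons
  writeLines(c("lab_id,instrument,date,level,day1_count,day2_count",
               "a,FACSCount,2013-01-01,low,300,310",
               "a,FACSCount,2013-01-02,low,abc,310",
               "a,FACSCount,not-a-date,low,300,310",
               "a,FACSCount,2013-01-04,middling,300,310"),
             file.path(dir, "bad.csv"))
  bad <- read_duplicate_csv(file.path(dir, "bad.csv"))
  expect_equal(nrow(bad$records), 1)
  expect_equal(bad$rejects$line, c(3L, 4L, 5L))
  expect_match(bad$rejects$reason[1], "day1_count.*abc")
  expect_match(bad$rejects$reason[2], "date")
  expect_match(bad$rejects$reason[3], "level")

  # a missing required column is a hard error
  writeLines("lab_id,date,level,day1_count", file.path(dir, "short.csv"))
  expect_error(read_duplicate_csv(file.path(dir, "short.csv")),
               "missing required column")
})

test_that("control CSVs round-trip through the readers", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(labs = lab_profile("L1", analytical_cv = 0.03,
                                              control_product = "IMMUNO-TROL"),
                           n_days = 60, seed = 3)
  ctl <- simulate_control_stream(cfg)
  write_qc_csv(ctl$runs, file.path(dir, "runs.csv"))
  write_qc_csv(ctl$lots, file.path(dir, "lots.csv"))
  runs <- read_control_runs_csv(file.path(dir, "runs.csv"))
  lots <- read_control_lots_csv(file.path(dir, "lots.csv"))
  expect_equal(nrow(runs$rejects), 0)
  expect_equal(as.data.frame(runs$records), as.data.frame(ctl$runs))
  expect_equal(lots$records$lot_id, ctl$lots$lot_id)
  res <- analyze_control_stream(runs$records, lots$records)
  expect_equal(nrow(res$evaluations), nrow(ctl$runs))
})

test_that("study summary matches the kernel statistics and flags missing methods", {
  cfg <- simulation_config(
    labs = dplyr::bind_rows(
      lab_profile("both", analytical_cv = 0.035,
                  control_product = "IMMUNO-TROL"),
      lab_profile("duponly", analytical_cv = 0.02)
    ),
    n_days = 90, seed = 19
  )
  v <- evaluate_pairs(simulate_duplicate_stream(cfg))
  ctl <- simulate_control_stream(cfg)
  ce <- analyze_control_stream(ctl$runs, ctl$lots)$evaluations
  s <- summarize_study(v, control_evaluations = ce)

  both <- s$per_lab[s$per_lab$lab_id == "both", ]
  only <- s$per_lab[s$per_lab$lab_id == "duponly", ]
  expect_false(is.na(both$ctrl_mean_cv))
  expect_true(is.na(only$ctrl_mean_cv))  # sentinel, never 0

  # summary equals the module statistics at full precision
  vb <- v[v$lab_id == "both" & v$status != "invalid", ]
  expect_equal(both$dup_mean_abs_pv, mean_abs_percent_variation(vb$pv))
  expect_equal(both$r_squared,
               regression_r2(vb$day1_count, vb$day2_count)$r_squared)
  expect_equal(both$ba_bias, bland_altman(vb$day1_count, vb$day2_count)$bias)

  # pooled failure rate consistency identity
  months <- c(both = 3, duponly = 3)
  expect_equal(duplicate_failure_rate(v, months)$rate_per_lab_year,
               failure_rate(sum(v$status == "fail"), 6)$rate_per_lab_year)

  fmt <- format_study_summary(s)
  expect_match(fmt$duplicate_pv[fmt$lab_id == "both"],
               "^[0-9.]+, [0-9.]+–[0-9.]+$")
  expect_equal(fmt$control_cv[fmt$lab_id == "duponly"], "–")
  expect_output(print(s), "failure rates per laboratory-year")
})

test_that("noise-free study summarises to zero variation and perfect correlation", {
  cfg <- simulation_config(labs = lab_profile("L1", analytical_cv = 0),
                           n_days = 60, seed = 5)
  v <- evaluate_pairs(simulate_duplicate_stream(cfg))
  s <- summarize_study(v)
  expect_equal(s$per_lab$dup_mean_abs_pv, 0)
  expect_equal(s$per_lab$r_squared, 1)
  expect_equal(s$failure_rates$rate_per_lab_year, 0)
})

test_that("chart exports carry their reference lines as columns", {
  cfg <- simulation_config(labs = lab_profile("L1", analytical_cv = 0.04,
                                              control_product = "IMMUNO-TROL"),
                           n_days = 90, seed = 37)
  v <- evaluate_pairs(simulate_duplicate_stream(cfg))

  pv <- export_chart_data("pv_trend", v, threshold = 20)
  expect_true(all(c("ref_zero", "ref_lower", "ref_upper") %in% names(pv)))
  expect_equal(unique(pv$ref_upper), 20)

  ba <- export_chart_data("bland_altman", v)
  for (lv in unique(ba$level)) {
    vb <- v[v$level == lv, ]
    ref <- bland_altman(vb$day1_count, vb$day2_count)
    sel <- ba[ba$level == lv, ]
    expect_equal(unique(sel$ref_bias), ref$bias)
    expect_equal(unique(sel$ref_loa_lower), ref$loa_lower)
    expect_equal(unique(sel$ref_loa_upper), ref$loa_upper)
  }

  ctl <- simulate_control_stream(cfg)
  res <- analyze_control_stream(ctl$runs, ctl$lots)
  lot <- res$lots[1, ]
  ev <- res$evaluations[res$evaluations$lot_id == lot$lot_id, ]
  lj <- export_chart_data("lj", ev, lot = lot)
  expect_true(all(c("mean", "sd1_lower", "sd1_upper", "sd2_lower",
                    "sd2_upper", "sd3_lower", "sd3_upper") %in% names(lj)))
  expect_equal(unique(lj$mean), lot$lab_mean)
  expect_equal(unique(lj$sd2_upper), lot$lab_mean + 2 * lot$lab_sd)

  rc <- export_chart_data("range_comparison", res$lots)
  expect_equal(rc$laboratory_high - rc$laboratory_low, 4 * res$lots$lab_sd)

  expect_error(export_chart_data("pie", v), "unknown chart kind")

  # writing to disk round-trips
  dir <- withr::local_tempdir()
  export_chart_data("cross_lab_trend", v,
                    path = file.path(dir, "trend.csv"))
  expect_true(file.exists(file.path(dir, "trend.csv")))
})

test_that("the command-line interface runs the simulate-analyze-summarize loop", {
  cli <- system.file("cli", "cd4iqc", package = "cd4iqc")
  dir <- withr::local_tempdir()
  libs <- paste(.libPaths(), collapse = .Platform$path.sep)
  run_cli <- function(...) {
    system2("Rscript", c(cli, ...), stdout = TRUE, stderr = TRUE,
            env = paste0("R_LIBS=", libs))
  }
  out1 <- run_cli("simulate", "--seed", "5", "--n-days", "60",
                  "--out-dir", dir)
  expect_true(file.exists(file.path(dir, "duplicate_pairs.csv")))
  expect_true(file.exists(file.path(dir, "control_runs.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))

  out2 <- run_cli("summarize", "--pairs", file.path(dir, "duplicate_pairs.csv"),
                  "--runs", file.path(dir, "control_runs.csv"),
                  "--lots", file.path(dir, "control_lots.csv"),
                  "--out-dir", dir)
  expect_true(file.exists(file.path(dir, "study_summary.csv")))
  expect_true(file.exists(file.path(dir, "failure_rates.csv")))

  # seed-respecting idempotence: same seed, byte-identical summary
  dir2 <- withr::local_tempdir()
  run_cli("simulate", "--seed", "5", "--n-days", "60", "--out-dir", dir2)
  run_cli("summarize", "--pairs", file.path(dir2, "duplicate_pairs.csv"),
          "--runs", file.path(dir2, "control_runs.csv"),
          "--lots", file.path(dir2, "control_lots.csv"), "--out-dir", dir2)
  expect_identical(readLines(file.path(dir, "study_summary.csv")),
                   readLines(file.path(dir2, "study_summary.csv")))
})
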