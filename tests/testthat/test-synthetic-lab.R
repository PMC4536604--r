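two_lab_config <- function(seed = 1, n_days = 60, cv = 0.04, ...) {
  simulation_config(
    labs = dplyr::bind_rows(
      lab_profile("L1", "FACSCount", analytical_cv = cv,
                  control_product = "IMMUNO-TROL"),
      lab_profile("L2", "Cyflow", analytical_cv = cv,
                  control_product = "Multi-Check")
    ),
    n_days = n_days, seed = seed, ...
  )
}

test_that("streams are deterministic under the seed and change with it", {
  cfg <- two_lab_config(seed = 100)
  a <- simulate_duplicate_stream(cfg)
  b <- simulate_duplicate_stream(cfg)
  expect_identical(a, b)
  ca <- simulate_control_stream(cfg)
  cb <- simulate_control_stream(cfg)
  expect_identical(ca, cb)
  # control stream does not depend on whether duplicates were drawn first
  set.seed(999); invisible(runif(10))
  expect_identical(simulate_control_stream(cfg), ca)

  other <- simulate_duplicate_stream(two_lab_config(seed = 101))
  expect_false(identical(a$day1_count, other$day1_count))
})

test_that("zero analytical noise collapses duplicates onto the truth", {
  cfg <- two_lab_config(cv = 0)
  dup <- simulate_duplicate_stream(cfg)
  expect_equal(dup$day1_count, dup$day2_count)
  v <- evaluate_pairs(dup)
  expect_true(all(v$pv == 0))
  expect_true(all(v$status == "pass"))

  ctl <- simulate_control_stream(cfg)
  means <- ctl$lots$manufacturer_mean[match(ctl$runs$lot_id, ctl$lots$lot_id)]
  expect_equal(ctl$runs$measured_count, means)
})

test_that("generated counts respect windows, rounding and positivity", {
  cfg <- two_lab_config(seed = 3)
  dup <- simulate_duplicate_stream(cfg)
  expect_true(all(dup$day1_count == round(dup$day1_count)))
  expect_true(all(dup$day1_count > 0 & dup$day2_count > 0))
  expect_true(all(dup$level %in% c("low", "normal")))
  # testing schedule: first 20 days of each month, both levels daily
  expect_equal(nrow(dup), 2 * 2 * sum(as.integer(format(
    seq(cfg$start_date, by = "day", length.out = cfg$n_days), "%d")) <= 20))

  # extreme noise forces resampling of would-be non-positive counts, logged
  loud <- simulation_config(labs = lab_profile("L1", analytical_cv = 0.49),
                            n_days = 365, seed = 4)
  expect_message(big <- simulate_duplicate_stream(loud), "resampled")
  expect_true(all(big$day1_count > 0 & big$day2_count > 0))
})

test_that("lots rotate at shelf-life expiry", {
  cfg <- two_lab_config(n_days = 90)
  ctl <- simulate_control_stream(cfg)
  mc_norm <- ctl$lots[ctl$lots$product == "Multi-Check" &
                        ctl$lots$level == "normal", ]
  it_norm <- ctl$lots[ctl$lots$product == "IMMUNO-TROL" &
                        ctl$lots$level == "normal", ]
  expect_equal(nrow(mc_norm), 3)  # 30-day shelf life over 90 days
  expect_equal(nrow(it_norm), 1)  # 90-day shelf life
  # every run's lot covers its date
  runs <- ctl$runs
  lot_row <- match(runs$lot_id, ctl$lots$lot_id)
  expect_true(all(runs$date >= ctl$lots$start_date[lot_row] &
                    runs$date <= ctl$lots$expiry[lot_row]))
})

test_that("duplicate %V spread matches a brute-force Monte-Carlo oracle", {
  cv <- 0.05
  cfg <- simulation_config(labs = lab_profile("L1", analytical_cv = cv,
                                              testing_days_per_month = 31),
                           n_days = 365 * 7, seed = 17)
  v <- evaluate_pairs(simulate_duplicate_stream(cfg))
  # independent oracle: the ratio of two Gaussian-noise replicates
  set.seed(18)
  t0 <- runif(2e5, 200, 1200)
  r1 <- t0 * (1 + rnorm(2e5, 0, cv))
  r2 <- t0 * (1 + rnorm(2e5, 0, cv))
  oracle_sd <- sd(100 * (r2 / r1 - 1))
  expect_lt(abs(sd(v$pv) - oracle_sd) / oracle_sd, 0.05)
  # mean |%V| recovery against the same large-n simulation
  oracle_mean_abs <- mean(abs(100 * (r2 / r1 - 1)))
  expect_lt(abs(mean_abs_percent_variation(v$pv) - oracle_mean_abs) /
              oracle_mean_abs, 0.05)
})

test_that("20-run establishment recovers the configured CV within chi-square bounds", {
  cfg <- simulation_config(labs = lab_profile("L1", analytical_cv = 0.03,
                                              control_product = "IMMUNO-TROL"),
                           n_days = 40, seed = 23)
  ctl <- simulate_control_stream(cfg)
  r <- ctl$runs[ctl$runs$lot_id == ctl$runs$lot_id[1], ]
  est <- establish_range(r[1:20, ])
  recovered <- est$lab_sd / est$lab_mean
  bounds <- 0.03 * sqrt(qchisq(c(0.005, 0.995), df = 19) / 19)
  expect_gt(recovered, bounds[1])
  expect_lt(recovered, bounds[2])
})

test_that("injected events follow their closed forms on noise-free streams", {
  cfg <- simulation_config(labs = lab_profile("L1", analytical_cv = 0),
                           n_days = 60, seed = 7, round_counts = FALSE)
  dup <- simulate_duplicate_stream(cfg)

  null_ev <- event_spec("shift", onset_day = 10, magnitude = 0, duration = 5)
  expect_equal(inject_event(dup, null_ev, cfg$start_date), dup)

  shifted <- inject_event(dup, event_spec("shift", 10, 0.25, duration = 1),
                          cfg$start_date)
  pv <- evaluate_pairs(shifted)$pv
  day_idx <- as.integer(dup$date - cfg$start_date) + 1
  expect_rel_equal(pv[day_idx == 10], rep(25, sum(day_idx == 10)))
  expect_true(all(pv[day_idx != 10] == 0))

  drift <- inject_event(dup, event_spec("drift", 20, -0.005, duration = 30),
                        cfg$start_date)
  pvd <- evaluate_pairs(drift)$pv
  hit <- day_idx >= 20 & day_idx <= 49
  expect_rel_equal(pvd[hit], 100 * (-0.005) * (day_idx[hit] - 20 + 1))
  expect_true(all(pvd[!hit] == 0))

  out <- inject_event(dup, event_spec("outlier", 30, 0.4), cfg$start_date)
  pvo <- evaluate_pairs(out)$pv
  expect_rel_equal(pvo[day_idx == 30], rep(40, sum(day_idx == 30)))
})

test_that("ground truth echoes the configuration and predicts cv=0 failures", {
  ev <- list(event_spec("outlier", 15, 0.25, lab_id = "L1",
                        target = "duplicate"))
  cfg <- two_lab_config(cv = 0, n_days = 30)
  cfg$events <- ev
  gt <- ground_truth(cfg)
  expect_equal(gt$labs$analytical_cv, c(0, 0))
  # one +25% outlier day, two levels, one lab
  expect_equal(gt$expected_duplicate_failures_cv0, 2L)
  v <- evaluate_pairs(simulate_duplicate_stream(cfg))
  expect_equal(sum(v$status == "fail"), gt$expected_duplicate_failures_cv0)

  quiet <- ground_truth(two_lab_config(cv = 0))
  expect_equal(quiet$expected_duplicate_failures_cv0, 0L)

  # sub-threshold events cause no cv=0 failures
  cfg$events <- list(event_spec("shift", 5, 0.1, duration = 10))
  expect_equal(ground_truth(cfg)$expected_duplicate_failures_cv0, 0L)
})

test_that("invalid configurations are rejected with the offending fields named", {
  expect_error(simulation_config(labs = lab_profile("L", analytical_cv = 0.03),
                                 n_days = 10,
                                 events = list(event_spec("shift", 50, 0.1))),
               "onset_day")
  expect_error(simulation_config(labs = tibble::tibble()), "labs")
  expect_error(lab_profile("L", analytical_cv = 0.6), "analytical_cv")
})

test_that("generated streams pass the pipeline validators unchanged", {
  cfg <- two_lab_config(seed = 29, n_days = 90)
  dup <- simulate_duplicate_stream(cfg)
  v <- evaluate_pairs(dup)
  expect_true(all(v$status != "invalid"))
  ctl <- simulate_control_stream(cfg)
  res <- analyze_control_stream(ctl$runs, ctl$lots)
  expect_equal(nrow(res$evaluations), nrow(ctl$runs))
})
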