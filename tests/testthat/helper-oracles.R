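# Independent brute-force oracles: every statistic re-implemented as an
# explicit loop over its textbook definition, kept free of any package code.

o_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}

o_sample_sd <- function(x) {
  m <- o_mean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  sqrt(s / (length(x) - 1))
}

o_cv <- function(x) o_sample_sd(x) / o_mean(x) * 100

o_mean_abs <- function(x) {
  s <- 0
  for (v in x) s <- s + abs(v)
  s / length(x)
}

o_pearson <- function(x, y) {
  mx <- o_mean(x); my <- o_mean(y)
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_along(x)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

o_bland_altman <- function(day1, day2, k_sd = 2) {
  d <- numeric(length(day1))
  for (i in seq_along(day1)) d[i] <- day2[i] - day1[i]
  bias <- o_mean(d)
  s <- o_sample_sd(d)
  list(bias = bias, sd_diff = s,
       loa_lower = bias - k_sd * s, loa_upper = bias + k_sd * s)
}

o_daily_mean_se <- function(dates, values) {
  out <- list()
  for (d in sort(unique(dates))) {
    v <- values[dates == d]
    se <- if (length(v) >= 2) o_sample_sd(v) / sqrt(length(v)) else NA_real_
    out[[length(out) + 1]] <- data.frame(date = d, n = length(v),
                                         mean = o_mean(v), se = se)
  }
  do.call(rbind, out)
}

# literal window scan over the six multirule definitions
o_westgard <- function(z) {
  n <- length(z)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    v <- character()
    if (abs(z[i]) > 2) v <- c(v, "1_2s")
    if (abs(z[i]) > 3) v <- c(v, "1_3s")
    if (i >= 2) {
      both_hi <- TRUE; both_lo <- TRUE
      for (j in (i - 1):i) {
        if (!(z[j] > 2)) both_hi <- FALSE
        if (!(z[j] < -2)) both_lo <- FALSE
      }
      if (both_hi || both_lo) v <- c(v, "2_2s")
      if ((z[i] > 2 && z[i - 1] < -2) || (z[i] < -2 && z[i - 1] > 2)) {
        v <- c(v, "R_4s")
      }
    }
    if (i >= 4) {
      hi <- TRUE; lo <- TRUE
      for (j in (i - 3):i) {
        if (!(z[j] > 1)) hi <- FALSE
        if (!(z[j] < -1)) lo <- FALSE
      }
      if (hi || lo) v <- c(v, "4_1s")
    }
    if (i >= 10) {
      hi <- TRUE; lo <- TRUE
      for (j in (i - 9):i) {
        if (!(z[j] > 0)) hi <- FALSE
        if (!(z[j] < 0)) lo <- FALSE
      }
      if (hi || lo) v <- c(v, "10_x")
    }
    res[[i]] <- v
  }
  res
}

# small duplicate-pair fixture builder
make_pairs <- function(day1, day2, lab_id = "labA", level = "normal",
                       dates = NULL, instrument = "FACSCount") {
  n <- length(day1)
  if (is.null(dates)) dates <- as.Date("2013-01-01") + seq_len(n) - 1
  duplicate_pairs(lab_id = rep(lab_id, n), instrument = instrument,
                  date = dates, level = rep(level, length.out = n),
                  day1_count = day1, day2_count = day2)
}

expect_rel_equal <- function(actual, expected, tol = 1e-9) {
  expect_true(all(abs(actual - expected) <=
                    tol * pmax(1, abs(expected))),
              label = paste0("relative agreement within ", tol))
}
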