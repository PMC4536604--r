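#' Laboratory profile for the synthetic QC generator
#'
#' Describes one simulated CD4 testing laboratory: its instrument, its
#' analytical imprecision (coefficient of variation on the relative scale,
#' e.g. 0.035 for 3.5%), an optional systematic relative bias, how many days
#' per calendar month it runs QC, and which commercial control product (if
#' any) it runs alongside duplicate analysis.
#'
#' @param lab_id Identifier.
#' @param instrument One of `"FACSCount"`, `"FACSCalibur"`, `"Cyflow"`,
#'   `"other"`.
#' @param analytical_cv Fraction in `[0, 0.5)`.
#' @param bias Systematic relative offset (fraction, default 0).
#' @param testing_days_per_month Integer in 1..31 (default 20).
#' @param control_product `NA` (duplicate analysis only) or a product name
#'   matching a configured control-lot specification.
#' @return One-row tibble.
#' @export
lab_profile <- function(lab_id, instrument = "other", analytical_cv,
                        bias = 0, testing_days_per_month = 20L,
                        control_product = NA_character_) {
  stopifnot(instrument %in% c("FACSCount", "FACSCalibur", "Cyflow", "other"),
            is.numeric(analytical_cv), analytical_cv >= 0, analytical_cv < 0.5,
            is.numeric(bias), is.finite(bias),
            testing_days_per_month >= 1, testing_days_per_month <= 31)
  tibble::tibble(lab_id = as.character(lab_id), instrument = instrument,
                 analytical_cv = analytical_cv, bias = bias,
                 testing_days_per_month = as.integer(testing_days_per_month),
                 control_product = as.character(control_product))
}

#' Out-of-control event specification
#'
#' An injectable departure from statistical control, emulating causes such
#' as reagent-lot changes, staff turnover, instrument drift or a one-off
#' processing error.
#'
#' @param kind `"shift"` (constant relative offset over `duration` days),
#'   `"drift"` (relative offset growing by `magnitude` per day over
#'   `duration` days; the first affected day already carries one day's
#'   drift), or `"outlier"` (a single affected day).
#' @param onset_day 1-based day index within the simulation horizon.
#' @param magnitude Fraction (shift/outlier) or fraction per day (drift).
#' @param duration Days affected (ignored for outliers).
#' @param lab_id Restrict to one laboratory (`NULL` = all labs).
#' @param target `"duplicate"`, `"control"` or `"both"` (default): which
#'   stream's measurements the event perturbs (day-2 re-test counts for the
#'   duplicate stream, control measurements for the control stream).
#' @return A list of class `"cd4iqc_event"`.
#' @export
event_spec <- function(kind = c("shift", "drift", "outlier"), onset_day,
                       magnitude, duration = 1L, lab_id = NULL,
                       target = c("both", "duplicate", "control")) {
  kind <- match.arg(kind)
  target <- match.arg(target)
  stopifnot(is.numeric(onset_day), onset_day >= 1,
            is.numeric(magnitude), is.finite(magnitude),
            is.numeric(duration), duration >= 1)
  structure(list(kind = kind, onset_day = as.integer(onset_day),
                 magnitude = magnitude, duration = as.integer(duration),
                 lab_id = if (is.null(lab_id)) NULL else as.character(lab_id),
                 target = target),
            class = "cd4iqc_event")
}

#' Control-lot specification for the generator
#'
#' @param product Product name (e.g. `"IMMUNO-TROL"`, `"Multi-Check"`).
#' @param level `"low"` or `"normal"`.
#' @param true_mean True (and manufacturer-assigned) mean count, cells/uL.
#' @param manufacturer_low,manufacturer_high Manufacturer range limits.
#' @param shelf_life_days Days a lot is used before rotating to a fresh lot.
#' @return One-row tibble.
#' @export
control_lot_spec <- function(product, level, true_mean,
                             manufacturer_low, manufacturer_high,
                             shelf_life_days) {
  stopifnot(level %in% c("low", "normal"), true_mean > 0,
            manufacturer_low <= true_mean, true_mean <= manufacturer_high,
            shelf_life_days >= 1)
  tibble::tibble(product = product, level = level, true_mean = true_mean,
                 manufacturer_low = manufacturer_low,
                 manufacturer_high = manufacturer_high,
                 shelf_life_days = as.integer(shelf_life_days))
}

#' Default control-lot specifications
#'
#' One low and one normal level per product: IMMUNO-TROL with a ~3-month
#' shelf life (long enough to establish a 20-run laboratory range) and
#' Multi-Check with a ~1-month shelf life (too short to establish one, so
#' QC decisions fall back on the wide manufacturer range).  Manufacturer
#' ranges default to +/-20% of the assigned mean.
#'
#' @return Tibble of [control_lot_spec()] rows.
#' @export
default_control_lots <- function() {
  dplyr::bind_rows(
    control_lot_spec("IMMUNO-TROL", "low", 300, 240, 360, 90L),
    control_lot_spec("IMMUNO-TROL", "normal", 800, 640, 960, 90L),
    control_lot_spec("Multi-Check", "low", 300, 240, 360, 30L),
    control_lot_spec("Multi-Check", "normal", 800, 640, 960, 30L)
  )
}

#' Simulation configuration
#'
#' Bundles everything the generator needs.  Given the same configuration and
#' seed the generated streams are identical.
#'
#' @param labs Tibble of [lab_profile()] rows.
#' @param n_days Simulation horizon in days (default 365).
#' @param seed Integer seed; the duplicate stream consumes `seed`, the
#'   control stream `seed + 1`, so each stream is reproducible regardless of
#'   the order the two are generated in.
#' @param start_date First calendar day (default 2013-01-01).
#' @param low_window Low-level true-count window, default `c(200, 400)`.
#' @param normal_range Normal-level true-count window, default `c(500, 1200)`.
#' @param threshold Duplicate-analysis acceptance limit in percent.
#' @param control_lots Tibble of [control_lot_spec()] rows.
#' @param events List of [event_spec()] objects.
#' @param error_model `"gaussian"` (relative noise `1 + N(bias, cv)`,
#'   default) or `"lognormal"` (`exp(N(log(1 + bias), cv))`).
#' @param round_counts Round generated counts to integers, as instruments
#'   report them (default `TRUE`); disable for exact algebraic checks.
#' @return A list of class `"cd4iqc_config"`.
#' @export
simulation_config <- function(labs, n_days = 365L, seed = 1L,
                              start_date = as.Date("2013-01-01"),
                              low_window = c(200, 400),
                              normal_range = c(500, 1200),
                              threshold = 20,
                              control_lots = default_control_lots(),
                              events = list(),
                              error_model = c("gaussian", "lognormal"),
                              round_counts = TRUE) {
  error_model <- match.arg(error_model)
  problems <- character()
  if (!is.data.frame(labs) || nrow(labs) == 0L) {
    problems <- c(problems, "labs: need at least one lab_profile() row")
  } else if (anyDuplicated(labs$lab_id)) {
    problems <- c(problems, "labs: lab_id values must be unique")
  }
  if (!is.numeric(n_days) || n_days < 1) problems <- c(problems, "n_days: must be >= 1")
  if (!is.numeric(seed) || !is.finite(seed)) problems <- c(problems, "seed: must be an integer")
  if (length(low_window) != 2L || low_window[1] > low_window[2]) {
    problems <- c(problems, "low_window: must be c(lo, hi) with lo <= hi")
  }
  if (length(normal_range) != 2L || normal_range[1] > normal_range[2]) {
    problems <- c(problems, "normal_range: must be c(lo, hi) with lo <= hi")
  }
  if (!is.numeric(threshold) || threshold <= 0) problems <- c(problems, "threshold: must be > 0")
  for (ev in events) {
    if (!inherits(ev, "cd4iqc_event")) {
      problems <- c(problems, "events: all entries must be event_spec() objects")
    } else if (ev$onset_day > n_days) {
      problems <- c(problems, sprintf("events: onset_day %d beyond horizon %d",
                                      ev$onset_day, as.integer(n_days)))
    }
  }
  if (length(problems)) {
    stop("invalid simulation config:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  structure(list(labs = tibble::as_tibble(labs), n_days = as.integer(n_days),
                 seed = as.integer(seed), start_date = as.Date(start_date),
                 low_window = low_window, normal_range = normal_range,
                 threshold = threshold,
                 control_lots = tibble::as_tibble(control_lots),
                 events = events, error_model = error_model,
                 round_counts = isTRUE(round_counts)),
            class = "cd4iqc_config")
}

#' Default 11-laboratory study configuration
#'
#' A year-long network of 11 CD4 testing laboratories: 3 FACSCount,
#' 5 FACSCalibur and 3 Cyflow instruments, all running daily duplicate
#' analysis, six additionally running a commercial control (one IMMUNO-TROL,
#' five Multi-Check).  Per-lab analytical CVs span ~0.4-6.4%, derived from
#' the mean absolute percent variations (0.5-7.2%) observed across such a
#' network via the half-normal identity E|%V| = (2/sqrt(pi)) * 100 * cv for
#' the difference of two cv-level noisy replicates.
#'
#' @param seed Integer seed.
#' @param n_days Horizon (default 365, one calendar year).
#' @param events Optional list of [event_spec()] objects.
#' @return A [simulation_config()].
#' @export
default_study_config <- function(seed = 1L, n_days = 365L, events = list()) {
  mean_pv <- c(2.43, 7.2, 5.7, 5.1, 4.4, 5.9, 2.6, 2.9, 0.5, 3.5, 4.8)
  instrument <- c("FACSCount", "FACSCount", "FACSCalibur", "FACSCalibur",
                  "FACSCalibur", "FACSCalibur", "FACSCount", "Cyflow",
                  "Cyflow", "Cyflow", "FACSCalibur")
  product <- c("IMMUNO-TROL", "Multi-Check", "Multi-Check", NA,
               "Multi-Check", "Multi-Check", "Multi-Check", NA, NA, NA, NA)
  cv <- mean_pv * sqrt(pi) / 200  # invert E|%V| = (2/sqrt(pi)) * 100 * cv
  labs <- dplyr::bind_rows(lapply(seq_along(mean_pv), function(i) {
    lab_profile(sprintf("lab%02d", i), instrument[i], analytical_cv = cv[i],
                control_product = product[i])
  }))
  simulation_config(labs, n_days = n_days, seed = seed, events = events)
}

# testing dates for one lab: the first k days of each calendar month inside
# the horizon
testing_dates <- function(config, testing_days_per_month) {
  all_days <- seq(config$start_date, by = "day", length.out = config$n_days)
  keep <- as.integer(format(all_days, "%d")) <= testing_days_per_month
  all_days[keep]
}

event_multiplier <- function(events, lab_id, day_idx, target) {
  mult <- rep(1, length(day_idx))
  for (ev in events) {
    if (!(ev$target %in% c(target, "both"))) next
    if (!is.null(ev$lab_id) && !(lab_id %in% ev$lab_id)) next
    if (ev$kind == "outlier") {
      hit <- day_idx == ev$onset_day
      mult[hit] <- mult[hit] * (1 + ev$magnitude)
    } else {
      last <- ev$onset_day + ev$duration - 1L
      hit <- day_idx >= ev$onset_day & day_idx <= last
      if (ev$kind == "shift") {
        mult[hit] <- mult[hit] * (1 + ev$magnitude)
      } else {  # drift
        mult[hit] <- mult[hit] *
          (1 + ev$magnitude * (day_idx[hit] - ev$onset_day + 1))
      }
    }
  }
  mult
}

# relative measurement noise factors, resampling any draw that would push a
# count to zero or below after rounding (logged via message)
noise_factors <- function(n, bias, cv, error_model, true_counts, round_counts) {
  draw <- function(k) {
    if (error_model == "gaussian") 1 + stats::rnorm(k, mean = bias, sd = cv)
    else exp(stats::rnorm(k, mean = log(1 + bias), sd = cv))
  }
  f <- draw(n)
  floor_val <- if (round_counts) 0.5 else .Machine$double.eps
  n_resampled <- 0L
  bad <- which(true_counts * f < floor_val)
  while (length(bad)) {
    n_resampled <- n_resampled + length(bad)
    f[bad] <- draw(length(bad))
    bad <- bad[true_counts[bad] * f[bad] < floor_val]
  }
  if (n_resampled > 0L) {
    message("resampled ", n_resampled,
            " noise draw(s) that would have produced non-positive counts")
  }
  f
}

#' Simulate a multi-laboratory duplicate-analysis stream
#'
#' For every laboratory, testing day and QC level, draws a true CD4 count
#' uniformly over the level's window (low: `low_window`; normal:
#' `normal_range`), then the day-1 and day-2 measurements as conditionally
#' independent noisy readings `true * (1 + N(bias, cv))`.  Configured events
#' perturb the day-2 measurement from their onset.  Counts are rounded to
#' integers unless `round_counts` is off.  Deterministic given the config
#' seed.
#'
#' @param config A [simulation_config()].
#' @return Duplicate-pair tibble: `lab_id`, `instrument`, `date`, `level`,
#'   `day1_count`, `day2_count`.
#' @export
simulate_duplicate_stream <- function(config) {
  stopifnot(inherits(config, "cd4iqc_config"))
  set.seed(config$seed)
  out <- lapply(seq_len(nrow(config$labs)), function(i) {
    lab <- config$labs[i, ]
    dates <- testing_dates(config, lab$testing_days_per_month)
    grid <- tidyr::expand_grid(date = dates, level = c("low", "normal"))
    n <- nrow(grid)
    win <- rbind(low = config$low_window, normal = config$normal_range)
    true <- stats::runif(n, win[grid$level, 1], win[grid$level, 2])
    f1 <- noise_factors(n, lab$bias, lab$analytical_cv, config$error_model,
                        true, config$round_counts)
    f2 <- noise_factors(n, lab$bias, lab$analytical_cv, config$error_model,
                        true, config$round_counts)
    day_idx <- as.integer(grid$date - config$start_date) + 1L
    mult <- event_multiplier(config$events, lab$lab_id, day_idx, "duplicate")
    d1 <- true * f1
    d2 <- true * f2 * mult
    if (config$round_counts) {
      d1 <- round(d1)
      d2 <- round(d2)
    }
    tibble::tibble(lab_id = lab$lab_id, instrument = lab$instrument,
                   date = grid$date, level = grid$level,
                   day1_count = d1, day2_count = d2)
  })
  dplyr::bind_rows(out)
}

#' Simulate commercial-control lots and runs
#'
#' Lots rotate at shelf-life expiry (a 30-day shelf life over a 90-day
#' horizon yields 3 successive lots per product and level).  Each laboratory
#' configured with a control product measures every level of that product
#' once per testing day: `true_mean * (1 + N(bias, cv))`, perturbed by
#' control-targeted events, rounded as configured.  Deterministic given the
#' config seed (+1, so the stream does not depend on whether the duplicate
#' stream was generated first).
#'
#' @param config A [simulation_config()].
#' @return List with `lots` (tibble: `lot_id`, `product`, `level`,
#'   `manufacturer_mean`, `manufacturer_low`, `manufacturer_high`,
#'   `start_date`, `expiry`) and `runs` (tibble: `lab_id`, `date`, `lot_id`,
#'   `measured_count`).
#' @export
simulate_control_stream <- function(config) {
  stopifnot(inherits(config, "cd4iqc_config"))
  set.seed(config$seed + 1L)
  specs <- config$control_lots
  lots <- dplyr::bind_rows(lapply(seq_len(nrow(specs)), function(i) {
    sp <- specs[i, ]
    n_lots <- ceiling(config$n_days / sp$shelf_life_days)
    start_off <- (seq_len(n_lots) - 1L) * sp$shelf_life_days
    tibble::tibble(
      lot_id = sprintf("%s-%s-%02d", sp$product, sp$level, seq_len(n_lots)),
      product = sp$product, level = sp$level,
      manufacturer_mean = sp$true_mean,
      manufacturer_low = sp$manufacturer_low,
      manufacturer_high = sp$manufacturer_high,
      start_date = config$start_date + start_off,
      expiry = config$start_date +
        pmin(start_off + sp$shelf_life_days, config$n_days) - 1L
    )
  }))
  ctrl_labs <- config$labs[!is.na(config$labs$control_product), , drop = FALSE]
  runs <- lapply(seq_len(nrow(ctrl_labs)), function(i) {
    lab <- ctrl_labs[i, ]
    lab_lots <- lots[lots$product == lab$control_product, , drop = FALSE]
    if (nrow(lab_lots) == 0L) {
      stop("lab ", lab$lab_id, " uses control product '", lab$control_product,
           "' but no lot spec defines it", call. = FALSE)
    }
    dates <- testing_dates(config, lab$testing_days_per_month)
    grid <- tidyr::expand_grid(date = dates,
                               level = unique(lab_lots$level))
    # active lot: the one whose [start, expiry] window covers the date
    lot_idx <- vapply(seq_len(nrow(grid)), function(j) {
      k <- which(lab_lots$level == grid$level[j] &
                 lab_lots$start_date <= grid$date[j] &
                 lab_lots$expiry >= grid$date[j])
      k[1]
    }, integer(1))
    lot_rows <- lab_lots[lot_idx, ]
    n <- nrow(grid)
    true <- lot_rows$manufacturer_mean
    f <- noise_factors(n, lab$bias, lab$analytical_cv, config$error_model,
                       true, config$round_counts)
    day_idx <- as.integer(grid$date - config$start_date) + 1L
    mult <- event_multiplier(config$events, lab$lab_id, day_idx, "control")
    x <- true * f * mult
    if (config$round_counts) x <- round(x)
    tibble::tibble(lab_id = lab$lab_id, date = grid$date,
                   lot_id = lot_rows$lot_id, measured_count = x)
  })
  list(lots = lots, runs = dplyr::bind_rows(runs))
}

#' Inject an out-of-control event into an existing stream
#'
#' Applies the event's multiplier to the stored measurements of a generated
#' stream: the day-2 count of a duplicate stream or the measured count of a
#' control-run stream.  Values are modified on the stored scale and not
#' re-rounded, so at zero analytical noise the induced percent variation is
#' the exact closed form of the event.
#'
#' @param stream A duplicate-pair or control-run tibble.
#' @param event An [event_spec()].
#' @param start_date Day-1 of the day-index scale (default: the earliest
#'   date in the stream).
#' @return The stream with affected measurements multiplied.
#' @export
inject_event <- function(stream, event, start_date = min(stream$date)) {
  stopifnot(inherits(event, "cd4iqc_event"), is.data.frame(stream),
            "date" %in% names(stream))
  col <- if ("day2_count" %in% names(stream)) "day2_count"
         else if ("measured_count" %in% names(stream)) "measured_count"
         else stop("stream has neither day2_count nor measured_count", call. = FALSE)
  day_idx <- as.integer(as.Date(stream$date) - as.Date(start_date)) + 1L
  lab <- if ("lab_id" %in% names(stream)) stream$lab_id else NULL
  mult <- rep(1, nrow(stream))
  for (l in unique(if (is.null(lab)) "" else lab)) {
    rows <- if (is.null(lab)) seq_len(nrow(stream)) else which(lab == l)
    mult[rows] <- event_multiplier(list(event), l, day_idx[rows],
                                   if (col == "day2_count") "duplicate" else "control")
  }
  stream[[col]] <- stream[[col]] * mult
  stream
}

#' Ground truth of a simulation configuration
#'
#' Machine-readable truth for parameter-recovery tests: per-lab analytical
#' CV and bias, the testing schedule size, the event table, and the number
#' of duplicate-analysis QC failures the configured events would cause on a
#' noise-free (cv = 0) stream.
#'
#' @param config A [simulation_config()].
#' @return List: `labs` (tibble with `lab_id`, `instrument`,
#'   `analytical_cv`, `bias`, `n_testing_days`, `lab_months`), `events`
#'   (tibble), `expected_duplicate_failures_cv0`, `threshold`, `seed`,
#'   `n_days`.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "cd4iqc_config"))
  labs <- dplyr::bind_rows(lapply(seq_len(nrow(config$labs)), function(i) {
    lab <- config$labs[i, ]
    dates <- testing_dates(config, lab$testing_days_per_month)
    tibble::tibble(lab_id = lab$lab_id, instrument = lab$instrument,
                   analytical_cv = lab$analytical_cv, bias = lab$bias,
                   n_testing_days = length(dates),
                   lab_months = length(unique(format(dates, "%Y-%m"))))
  }))
  n_levels <- 2L
  expected <- 0L
  for (i in seq_len(nrow(config$labs))) {
    lab <- config$labs[i, ]
    dates <- testing_dates(config, lab$testing_days_per_month)
    day_idx <- as.integer(dates - config$start_date) + 1L
    mult <- event_multiplier(config$events, lab$lab_id, day_idx, "duplicate")
    expected <- expected +
      n_levels * sum(abs(100 * (mult - 1)) > config$threshold)
  }
  events <- if (length(config$events)) {
    dplyr::bind_rows(lapply(config$events, function(ev) {
      tibble::tibble(kind = ev$kind, onset_day = ev$onset_day,
                     magnitude = ev$magnitude, duration = ev$duration,
                     lab_id = if (is.null(ev$lab_id)) NA_character_ else ev$lab_id,
                     target = ev$target)
    }))
  } else {
    tibble::tibble(kind = character(), onset_day = integer(),
                   magnitude = double(), duration = integer(),
                   lab_id = character(), target = character())
  }
  list(labs = labs, events = events,
       expected_duplicate_failures_cv0 = as.integer(expected),
       threshold = config$threshold, seed = config$seed,
       n_days = config$n_days)
}
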