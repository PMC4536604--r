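#' Eligibility of a day-1 sample for a QC level
#'
#' Duplicate-analysis IQC carries over one low and one normal patient sample
#' from the previous day.  A sample is eligible for the low level when its
#' day-1 count lies in the closed window 200-400 cells/uL and for the normal
#' level when it exceeds 500 cells/uL; counts in (400, 500] qualify for
#' neither level.
#'
#' @param level Character vector, `"low"` or `"normal"`.
#' @param day1_count Day-1 counts (cells/uL), strictly positive.
#' @param low_window Closed low-level window, default `c(200, 400)`.
#' @param normal_floor Exclusive lower bound for the normal level, default 500.
#' @return Logical vector.
#' @export
check_eligibility <- function(level, day1_count,
                              low_window = c(200, 400), normal_floor = 500) {
  stopifnot(length(low_window) == 2L, low_window[1] <= low_window[2])
  if (length(level) == 1L && length(day1_count) > 1L) {
    level <- rep(level, length(day1_count))
  }
  if (length(level) != length(day1_count)) stop("length mismatch", call. = FALSE)
  if (!all(level %in% c("low", "normal"))) {
    stop("unknown QC level: ", paste(unique(setdiff(level, c("low", "normal"))),
                                     collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(day1_count) | day1_count <= 0)) {
    stop("day-1 counts must be finite and > 0", call. = FALSE)
  }
  ifelse(level == "low",
         day1_count >= low_window[1] & day1_count <= low_window[2],
         day1_count > normal_floor)
}

#' Build a duplicate-pair table
#'
#' Convenience constructor enforcing the duplicate-pair record schema used
#' throughout the package.
#'
#' @param lab_id,instrument,date,level,day1_count,day2_count Column vectors;
#'   `date` is coerced with [as.Date()].
#' @return A tibble with the canonical column order.
#' @export
duplicate_pairs <- function(lab_id, instrument = "other", date, level,
                            day1_count, day2_count) {
  tibble::tibble(
    lab_id = as.character(lab_id),
    instrument = as.character(instrument),
    date = as.Date(date),
    level = as.character(level),
    day1_count = as.numeric(day1_count),
    day2_count = as.numeric(day2_count)
  )
}

#' Evaluate duplicate pairs into QC verdicts
#'
#' Computes the percent variation for every pair and classifies each as
#' `pass`, `fail`, or `invalid`.  Invalid records (non-positive or missing
#' day-1 count, negative or missing day-2 count, unknown level, ineligible
#' day-1 count when eligibility is enforced, or a second same-day record for
#' the same laboratory and level) are flagged with a reason and kept in
#' place, never dropped.
#'
#' @param pairs Duplicate-pair data frame (see [duplicate_pairs()]).
#' @param threshold Acceptance limit in percent (default 20).
#' @param enforce_eligibility Also invalidate pairs whose day-1 count falls
#'   outside the level's eligibility window (default `FALSE`: historical logs
#'   are evaluated as recorded).
#' @param low_window,normal_floor Eligibility windows passed to
#'   [check_eligibility()].
#' @return The input with added columns `pv`, `acceptable`, `status`
#'   (`pass`/`fail`/`invalid`) and `reason` (`NA` unless invalid), one row
#'   per input row in input order.
#' @export
evaluate_pairs <- function(pairs, threshold = 20, enforce_eligibility = FALSE,
                           low_window = c(200, 400), normal_floor = 500) {
  pairs <- validate_pair_columns(pairs)
  n <- nrow(pairs)
  reason <- rep(NA_character_, n)

  bad_level <- !(pairs$level %in% c("low", "normal"))
  reason[bad_level] <- "unknown level"
  bad_d1 <- !is.finite(pairs$day1_count) | pairs$day1_count <= 0
  reason[bad_d1 & is.na(reason)] <- "day1_count must be > 0"
  bad_d2 <- !is.finite(pairs$day2_count) | pairs$day2_count < 0
  reason[bad_d2 & is.na(reason)] <- "day2_count must be >= 0"

  if (enforce_eligibility) {
    ok_row <- is.na(reason)
    if (any(ok_row)) {
      elig <- check_eligibility(pairs$level[ok_row], pairs$day1_count[ok_row],
                                low_window, normal_floor)
      idx <- which(ok_row)[!elig]
      reason[idx] <- "day1_count outside eligibility window for level"
    }
  }

  # one pair per lab, level and day: later same-day records are data errors
  key <- paste(pairs$lab_id, pairs$level, pairs$date, sep = "\r")
  dup <- duplicated(key)
  reason[dup & is.na(reason)] <- "duplicate record for lab/level/day"

  pv <- rep(NA_real_, n)
  acceptable <- rep(NA, n)
  ok <- is.na(reason)
  if (any(ok)) {
    res <- percent_variation(pairs$day1_count[ok], pairs$day2_count[ok],
                             threshold = threshold)
    pv[ok] <- res$value
    acceptable[ok] <- res$acceptable
  }
  status <- ifelse(!ok, "invalid", ifelse(acceptable, "pass", "fail"))
  dplyr::mutate(pairs, pv = pv, acceptable = acceptable,
                status = status, reason = reason)
}

validate_pair_columns <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  need <- c("lab_id", "date", "level", "day1_count", "day2_count")
  missing <- setdiff(need, names(pairs))
  if (length(missing)) {
    stop("missing duplicate-pair columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"instrument" %in% names(pairs)) pairs$instrument <- "other"
  pairs$date <- as.Date(pairs$date)
  tibble::as_tibble(pairs)
}

#' Long-term precision summary for one laboratory
#'
#' Per QC level: mean absolute percent variation, the range (min, max) of
#' calendar-monthly mean absolute percent variations, regression r-squared,
#' Bland-Altman bias and limits of agreement, pair and failure counts, and
#' the failure rate over the months the laboratory contributed.  Levels with
#' fewer than 3 valid pairs are reported with the statistics unavailable
#' (`NA`), never silently dropped.
#'
#' @param pairs Duplicate-pair data frame for a single laboratory.
#' @param threshold Acceptance limit in percent (default 20).
#' @param k_sd Limits-of-agreement multiplier (default 2).
#' @return Tibble with one row per level: `lab_id`, `level`, `period_start`,
#'   `period_end`, `n_pairs`, `n_failures`, `n_invalid`, `mean_abs_pv`,
#'   `pv_range_min`, `pv_range_max` (monthly means), `pearson_r`,
#'   `r_squared`, `bias`, `sd_diff`, `loa_lower`, `loa_upper`, `lab_months`,
#'   `failure_rate_per_lab_year`.
#' @export
long_term_precision <- function(pairs, threshold = 20, k_sd = 2) {
  verdicts <- evaluate_pairs(pairs, threshold = threshold)
  if (length(unique(verdicts$lab_id)) > 1L) {
    stop("`long_term_precision()` summarises one laboratory; got ",
         length(unique(verdicts$lab_id)), call. = FALSE)
  }
  per_level <- lapply(c("low", "normal"), function(lv) {
    v <- verdicts[verdicts$level == lv, , drop = FALSE]
    valid <- v[v$status != "invalid", , drop = FALSE]
    months <- length(unique(format(valid$date, "%Y-%m")))
    base <- tibble::tibble(
      lab_id = unique(verdicts$lab_id),
      level = lv,
      period_start = if (nrow(valid)) min(valid$date) else as.Date(NA),
      period_end = if (nrow(valid)) max(valid$date) else as.Date(NA),
      n_pairs = nrow(v),
      n_failures = sum(v$status == "fail"),
      n_invalid = sum(v$status == "invalid"),
      mean_abs_pv = NA_real_, pv_range_min = NA_real_, pv_range_max = NA_real_,
      pearson_r = NA_real_, r_squared = NA_real_,
      bias = NA_real_, sd_diff = NA_real_,
      loa_lower = NA_real_, loa_upper = NA_real_,
      lab_months = months,
      failure_rate_per_lab_year = if (months > 0)
        failure_rate(sum(v$status == "fail"), months)$rate_per_lab_year
      else NA_real_
    )
    if (nrow(valid) < 3L) return(base)  # level unavailable
    monthly <- tapply(abs(valid$pv), format(valid$date, "%Y-%m"), mean)
    base$mean_abs_pv <- mean_abs_percent_variation(valid$pv)
    base$pv_range_min <- min(monthly)
    base$pv_range_max <- max(monthly)
    reg <- tryCatch(regression_r2(valid$day1_count, valid$day2_count),
                    error = function(e) list(pearson_r = NA_real_,
                                             r_squared = NA_real_))
    base$pearson_r <- reg$pearson_r
    base$r_squared <- reg$r_squared
    ba <- bland_altman(valid$day1_count, valid$day2_count, k_sd = k_sd)
    base$bias <- ba$bias
    base$sd_diff <- ba$sd_diff
    base$loa_lower <- ba$loa_lower
    base$loa_upper <- ba$loa_upper
    base
  })
  dplyr::bind_rows(per_level)
}

#' Percent-variation trend series for one laboratory
#'
#' Chronologically sorted per-day, per-level percent variations with the 0%
#' centre line and the +/-threshold acceptance lines as columns, ready for a
#' trend chart.  Gaps (days without a pair) are preserved, not interpolated.
#'
#' @param verdicts Output of [evaluate_pairs()] for a single laboratory.
#' @param threshold Acceptance limit in percent (default 20).
#' @return Tibble: `date`, `level`, `pv`, `status`, `ref_zero`, `ref_lower`,
#'   `ref_upper`, sorted ascending by date within level.
#' @export
pv_trend_series <- function(verdicts, threshold = 20) {
  stopifnot(is.data.frame(verdicts), all(c("date", "level", "pv") %in% names(verdicts)))
  if (length(unique(verdicts$lab_id)) > 1L) {
    stop("`pv_trend_series()` expects verdicts from one laboratory", call. = FALSE)
  }
  out <- tibble::tibble(
    date = as.Date(verdicts$date),
    level = verdicts$level,
    pv = verdicts$pv,
    status = if ("status" %in% names(verdicts)) verdicts$status else NA_character_,
    ref_zero = 0,
    ref_lower = -threshold,
    ref_upper = threshold
  )
  dplyr::arrange(out, .data$level, .data$date)
}

#' Cross-laboratory daily percent-variation trend
#'
#' For each calendar day and QC level, the mean and standard error of the
#' percent variations reported by the participating laboratories; the series
#' of an in-control network fluctuates around 0%.
#'
#' @param verdicts Output of [evaluate_pairs()] over all laboratories.
#' @return Tibble: `level`, `date`, `n_labs`, `mean`, `se` (SE `NA` on days
#'   with a single laboratory).
#' @export
cross_lab_trend <- function(verdicts) {
  stopifnot(is.data.frame(verdicts), all(c("date", "level", "pv") %in% names(verdicts)))
  valid <- verdicts[is.finite(verdicts$pv), , drop = FALSE]
  out <- lapply(split(valid, valid$level), function(d) {
    dplyr::mutate(daily_mean_se(d, value_col = "pv", date_col = "date"),
                  level = unique(d$level), .before = 1)
  })
  dplyr::bind_rows(out)
}

#' Pooled duplicate-analysis QC failure rate
#'
#' Counts failing verdicts across all laboratories and divides by the total
#' laboratory observation time.
#'
#' @param verdicts Output of [evaluate_pairs()] over all laboratories.
#' @param contributed_months Data frame with columns `lab_id` and `months`
#'   (or a named numeric vector); every laboratory present in `verdicts`
#'   must have a positive entry.
#' @return One-row tibble as [failure_rate()].
#' @export
duplicate_failure_rate <- function(verdicts, contributed_months) {
  months <- normalize_months(contributed_months)
  labs <- unique(verdicts$lab_id)
  missing <- setdiff(labs, names(months))
  if (length(missing)) {
    stop("no contributed months for laboratories: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  failure_rate(sum(verdicts$status == "fail"), sum(months[labs]))
}

normalize_months <- function(contributed_months) {
  if (is.data.frame(contributed_months)) {
    stopifnot(all(c("lab_id", "months") %in% names(contributed_months)))
    months <- stats::setNames(as.numeric(contributed_months$months),
                              as.character(contributed_months$lab_id))
  } else {
    stopifnot(is.numeric(contributed_months), !is.null(names(contributed_months)))
    months <- contributed_months
  }
  if (any(!is.finite(months) | months <= 0)) {
    stop("contributed months must all be > 0", call. = FALSE)
  }
  months
}
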