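#' Percent variation between a duplicate pair of CD4 counts
#'
#' The daily acceptance statistic of the duplicate-analysis IQC method:
#' a previous-day sample is re-tested and the day-2 (observed) count is
#' compared with the day-1 (expected) count as
#' \deqn{\%V = \frac{\mathrm{observed}}{\mathrm{expected}} \times 100 - 100.}
#' A run is acceptable when \eqn{|\%V|} does not exceed the threshold
#' (inclusive: \eqn{|\%V| = 20} passes at the default threshold).
#'
#' @param expected Day-1 CD4 counts (cells/uL); must be strictly positive.
#' @param observed Day-2 CD4 counts (cells/uL); must be non-negative.
#' @param threshold Acceptance limit in percent (default 20).
#' @return A tibble with one row per pair and columns `value` (signed
#'   percent) and `acceptable` (logical).
#' @examples
#' percent_variation(500, 600)          # +20%, acceptable (boundary inclusive)
#' percent_variation(400, 300)$value    # -25
#' @export
percent_variation <- function(expected, observed, threshold = 20) {
  if (length(expected) != length(observed)) {
    stop("`expected` and `observed` must have the same length", call. = FALSE)
  }
  if (length(expected) == 0L) stop("empty input", call. = FALSE)
  if (!all(is.finite(expected)) || !all(is.finite(observed))) {
    stop("counts must be finite", call. = FALSE)
  }
  if (any(expected <= 0)) {
    stop("invalid record: day-1 (expected) count must be > 0", call. = FALSE)
  }
  if (any(observed < 0)) {
    stop("invalid record: day-2 (observed) count must be >= 0", call. = FALSE)
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  value <- observed / expected * 100 - 100
  tibble::tibble(value = value, acceptable = abs(value) <= threshold)
}

#' Mean absolute percent variation
#'
#' Long-term precision summary of duplicate analysis: the arithmetic mean of
#' the daily percent variations after discarding their sign.
#'
#' @param pv Numeric vector of signed percent variations.
#' @return The mean of `abs(pv)`, in percent.
#' @export
mean_abs_percent_variation <- function(pv) {
  if (length(pv) == 0L) stop("empty percent-variation series", call. = FALSE)
  if (!all(is.finite(pv))) stop("percent variations must be finite", call. = FALSE)
  mean(abs(pv))
}

#' Coefficient of variation (%CV)
#'
#' Precision statistic for repeated control measurements: sample standard
#' deviation (n - 1 denominator) over the mean, times 100.
#'
#' @param values Numeric vector of counts (cells/uL); at least two values
#'   with a strictly positive mean.
#' @return The %CV, in percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) {
    stop("insufficient data: %CV needs at least 2 values", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  m <- mean(values)
  if (m <= 0) stop("%CV undefined: mean must be > 0", call. = FALSE)
  stats::sd(values) / m * 100
}

#' Pearson correlation and r-squared of a duplicate series
#'
#' Long-term precision of duplicate analysis is judged by the coefficient of
#' determination of the simple linear regression of day-2 on day-1 counts,
#' which for a single predictor equals the squared Pearson correlation.
#'
#' @param day1 Day-1 counts.
#' @param day2 Day-2 counts, same length (at least 3 pairs, both series with
#'   nonzero variance).
#' @return A list with `pearson_r` and `r_squared`.
#' @export
regression_r2 <- function(day1, day2) {
  if (length(day1) != length(day2)) stop("length mismatch", call. = FALSE)
  if (length(day1) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (!all(is.finite(day1)) || !all(is.finite(day2))) {
    stop("counts must be finite", call. = FALSE)
  }
  if (stats::var(day1) == 0 || stats::var(day2) == 0) {
    stop("degenerate input: zero variance, correlation undefined", call. = FALSE)
  }
  r <- stats::cor(day1, day2)
  list(pearson_r = r, r_squared = r^2)
}

#' Bland-Altman agreement analysis
#'
#' Agreement between day-1 and day-2 counts: differences are taken as
#' day2 - day1 (observed minus expected, matching the percent-variation sign
#' convention), the bias is their mean, and the limits of agreement are
#' bias +/- `k_sd` sample standard deviations (default exactly 2).
#'
#' @param day1,day2 Paired counts, equal length >= 2.
#' @param k_sd Multiplier for the limits of agreement (default 2).
#' @return One-row tibble: `bias`, `sd_diff`, `loa_lower`, `loa_upper`,
#'   `n_pairs` (all count columns in cells/uL).
#' @export
bland_altman <- function(day1, day2, k_sd = 2) {
  if (length(day1) != length(day2)) stop("length mismatch", call. = FALSE)
  if (length(day1) < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (!all(is.finite(day1)) || !all(is.finite(day2))) {
    stop("counts must be finite", call. = FALSE)
  }
  stopifnot(is.numeric(k_sd), length(k_sd) == 1L, k_sd >= 0)
  d <- day2 - day1
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  tibble::tibble(
    bias = bias,
    sd_diff = sd_diff,
    loa_lower = bias - k_sd * sd_diff,
    loa_upper = bias + k_sd * sd_diff,
    n_pairs = length(d)
  )
}

#' QC failure rate per laboratory-year
#'
#' Number of QC failures across laboratories divided by the total observation
#' time they contributed.  Observation time arrives in laboratory-months; the
#' primary rate converts it to laboratory-years (months / 12) because the
#' quantity is conventionally reported per laboratory-year, and the raw
#' per-laboratory-month rate is returned alongside.
#'
#' @param n_failures Non-negative failure count.
#' @param lab_months Total months contributed by all laboratories (> 0).
#' @return One-row tibble: `n_failures`, `lab_months`, `rate_per_lab_year`,
#'   `rate_per_lab_month`.
#' @export
failure_rate <- function(n_failures, lab_months) {
  stopifnot(length(n_failures) == 1L, length(lab_months) == 1L)
  if (!is.finite(n_failures) || n_failures < 0) {
    stop("`n_failures` must be a non-negative number", call. = FALSE)
  }
  if (!is.finite(lab_months) || lab_months <= 0) {
    stop("`lab_months` must be > 0", call. = FALSE)
  }
  tibble::tibble(
    n_failures = n_failures,
    lab_months = lab_months,
    rate_per_lab_year = n_failures / (lab_months / 12),
    rate_per_lab_month = n_failures / lab_months
  )
}

#' Daily cross-laboratory mean and standard error
#'
#' For each calendar day with at least one observation, the mean and standard
#' error (sample sd / sqrt(n)) of that day's percent variations across
#' laboratories.  Days without observations are omitted, never zero-filled;
#' the SE is `NA` on days contributed by a single laboratory.
#'
#' @param data A data frame with one row per laboratory-day.
#' @param value_col Name of the percent-variation column (default `"pv"`).
#' @param date_col Name of the calendar-day column (default `"date"`).
#' @return Tibble with `date`, `n_labs`, `mean`, `se`, sorted by date.
#' @export
daily_mean_se <- function(data, value_col = "pv", date_col = "date") {
  stopifnot(is.data.frame(data))
  if (!all(c(value_col, date_col) %in% names(data))) {
    stop("`data` must contain columns `", date_col, "` and `", value_col, "`",
         call. = FALSE)
  }
  data <- data[is.finite(data[[value_col]]), , drop = FALSE]
  if (nrow(data) == 0L) {
    return(tibble::tibble(date = as.Date(character()), n_labs = integer(),
                          mean = double(), se = double()))
  }
  out <- dplyr::summarise(
    dplyr::group_by(data, date = .data[[date_col]]),
    n_labs = dplyr::n(),
    mean = mean(.data[[value_col]]),
    se = ifelse(dplyr::n() >= 2L,
                stats::sd(.data[[value_col]]) / sqrt(dplyr::n()),
                NA_real_),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$date)
}
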