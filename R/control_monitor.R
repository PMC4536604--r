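#' Build a control-lot record
#'
#' A stabilized commercial control material (e.g. IMMUNO-TROL, Multi-Check)
#' with the manufacturer's assigned mean and range, and optionally a
#' laboratory-established range (`lab_mean` +/- 2 `lab_sd`) with
#' `range_status` `"none"`, `"provisional"` (>= 10 establishment runs) or
#' `"final"` (>= 20 runs).
#'
#' @param lot_id Lot identifier.
#' @param product Product name (e.g. `"IMMUNO-TROL"`, `"Multi-Check"`).
#' @param level QC level, `"low"` or `"normal"`.
#' @param manufacturer_mean,manufacturer_low,manufacturer_high Assigned mean
#'   and range limits (cells/uL), `low <= mean <= high`.
#' @param lab_mean,lab_sd Laboratory-established mean and sample sd, if any.
#' @param range_status `"none"`, `"provisional"` or `"final"`.
#' @return One-row tibble.
#' @export
control_lot <- function(lot_id, product = "other", level,
                        manufacturer_mean, manufacturer_low, manufacturer_high,
                        lab_mean = NA_real_, lab_sd = NA_real_,
                        range_status = "none") {
  stopifnot(level %in% c("low", "normal"),
            range_status %in% c("none", "provisional", "final"))
  if (!(manufacturer_low <= manufacturer_mean &&
        manufacturer_mean <= manufacturer_high)) {
    stop("manufacturer range must satisfy low <= mean <= high", call. = FALSE)
  }
  tibble::tibble(
    lot_id = as.character(lot_id), product = as.character(product),
    level = level,
    manufacturer_mean = as.numeric(manufacturer_mean),
    manufacturer_low = as.numeric(manufacturer_low),
    manufacturer_high = as.numeric(manufacturer_high),
    lab_mean = as.numeric(lab_mean), lab_sd = as.numeric(lab_sd),
    range_status = range_status
  )
}

#' Establish a laboratory range for a control lot
#'
#' Computes the laboratory-established range (mean +/- 2 sample sd) from the
#' lot's establishment runs: at least 10 runs for a provisional range, at
#' least 20 for the final range.
#'
#' @param runs Control-run data frame for a single lot (columns `lot_id`,
#'   `measured_count`; a bare numeric vector of counts is also accepted).
#' @param lot One-row control-lot tibble to update (optional; omit to get
#'   just the range statistics).
#' @param mode `"final"` (default) or `"provisional"`.
#' @return If `lot` is supplied, the updated one-row lot tibble; otherwise a
#'   list with `lab_mean`, `lab_sd`, `lab_low`, `lab_high`, `range_status`,
#'   `n_runs` and `degenerate` (TRUE when the sd is zero).
#' @export
establish_range <- function(runs, lot = NULL, mode = c("final", "provisional")) {
  mode <- match.arg(mode)
  if (is.data.frame(runs)) {
    if (!"measured_count" %in% names(runs)) {
      stop("`runs` must have a `measured_count` column", call. = FALSE)
    }
    if ("lot_id" %in% names(runs) && length(unique(runs$lot_id)) > 1L) {
      stop("establishment runs must come from a single lot", call. = FALSE)
    }
    x <- as.numeric(runs$measured_count)
  } else {
    x <- as.numeric(runs)
  }
  need <- if (mode == "final") 20L else 10L
  if (length(x) < need) {
    stop("insufficient data: ", mode, " range requires at least ", need,
         " runs, got ", length(x), call. = FALSE)
  }
  m <- mean(x)
  s <- stats::sd(x)
  res <- list(lab_mean = m, lab_sd = s, lab_low = m - 2 * s,
              lab_high = m + 2 * s, range_status = mode,
              n_runs = length(x), degenerate = s == 0)
  if (res$degenerate) {
    warning("degenerate laboratory range: establishment runs have zero spread",
            call. = FALSE)
  }
  if (is.null(lot)) return(res)
  stopifnot(is.data.frame(lot), nrow(lot) == 1L)
  lot$lab_mean <- m
  lot$lab_sd <- s
  lot$range_status <- mode
  lot
}

#' Active range of a control lot
#'
#' The laboratory-established range when one exists (optionally only when
#' final), else the manufacturer's range.  Range limits are inclusive.
#'
#' @param lot One-row control-lot tibble.
#' @param use_provisional Accept a provisional laboratory range for QC
#'   decisions (default `FALSE`: only final ranges are used, provisional
#'   ranges remain informational).
#' @return List: `source` (`"laboratory"` or `"manufacturer"`), `low`,
#'   `high`, `mean`, `sd` (`NA` for manufacturer ranges).
#' @export
active_range <- function(lot, use_provisional = FALSE) {
  stopifnot(is.data.frame(lot), nrow(lot) == 1L)
  ok_status <- if (use_provisional) c("provisional", "final") else "final"
  if (!is.na(lot$lab_mean) && !is.na(lot$lab_sd) &&
      lot$range_status %in% ok_status) {
    return(list(source = "laboratory",
                low = lot$lab_mean - 2 * lot$lab_sd,
                high = lot$lab_mean + 2 * lot$lab_sd,
                mean = lot$lab_mean, sd = lot$lab_sd))
  }
  if (is.na(lot$manufacturer_low) || is.na(lot$manufacturer_high)) {
    stop("lot has no usable range", call. = FALSE)
  }
  list(source = "manufacturer", low = lot$manufacturer_low,
       high = lot$manufacturer_high, mean = lot$manufacturer_mean,
       sd = NA_real_)
}

#' Levey-Jennings evaluation of control runs
#'
#' Evaluates each run of one lot against the lot's active range: `in_range`
#' tests the measured count against the inclusive range limits, `z_score` is
#' available only when a laboratory range (with sd) is active, and Westgard
#' multirule violations are flagged from the chronological z-score history.
#'
#' @param runs Control-run data frame (columns `lab_id`, `date`, `lot_id`,
#'   `measured_count`) for the single lot described by `lot`.
#' @param lot One-row control-lot tibble.
#' @param use_provisional Passed to [active_range()].
#' @param rules Westgard rejection rules to apply, see [westgard_evaluate()].
#' @return The runs, sorted chronologically, with added columns `z_score`,
#'   `in_range`, `active_range`, `violations` (semicolon-joined rule ids,
#'   `""` when none).
#' @export
evaluate_runs <- function(runs, lot, use_provisional = FALSE,
                          rules = c("1_2s", "1_3s", "2_2s", "R_4s", "4_1s", "10_x")) {
  stopifnot(is.data.frame(runs),
            all(c("date", "lot_id", "measured_count") %in% names(runs)))
  if (any(runs$lot_id != lot$lot_id)) {
    stop("runs reference a different lot than `lot`", call. = FALSE)
  }
  if (any(!is.finite(runs$measured_count) | runs$measured_count < 0)) {
    stop("measured counts must be finite and >= 0", call. = FALSE)
  }
  rng <- active_range(lot, use_provisional = use_provisional)
  runs <- dplyr::arrange(tibble::as_tibble(runs), as.Date(.data$date))
  runs$date <- as.Date(runs$date)
  x <- runs$measured_count
  runs$z_score <- if (!is.na(rng$sd) && rng$sd > 0) (x - rng$mean) / rng$sd
                  else NA_real_
  runs$in_range <- x >= rng$low & x <= rng$high
  runs$active_range <- rng$source
  if (all(is.finite(runs$z_score))) {
    viol <- westgard_evaluate(runs$z_score, rules = rules)
    runs$violations <- vapply(viol, paste, "", collapse = ";")
  } else {
    runs$violations <- ""
  }
  runs
}

#' Monthly coefficient of variation for a control lot
#'
#' The %CV of the measured counts within each calendar month, computed at
#' month end as a precision statistic; months with fewer than 2 runs are
#' reported with `cv` unavailable (`NA`).
#'
#' @param runs Control-run data frame for one lot (or one lot and lab).
#' @return Tibble: `month` (`"YYYY-MM"`), `n_runs`, `cv`.
#' @export
monthly_cv <- function(runs) {
  stopifnot(is.data.frame(runs),
            all(c("date", "measured_count") %in% names(runs)))
  month <- format(as.Date(runs$date), "%Y-%m")
  out <- lapply(split(runs$measured_count, month), function(x) {
    tibble::tibble(n_runs = length(x),
                   cv = if (length(x) >= 2L) coefficient_of_variation(x)
                        else NA_real_)
  })
  dplyr::bind_rows(out, .id = "month")
}

#' Compare the manufacturer and laboratory ranges of a lot
#'
#' Manufacturer ranges are typically wide; the laboratory-established
#' mean +/- 2 sd range is what daily QC decisions should rest on.  Reports
#' both widths and the offset between the two means.
#'
#' @param lot One-row control-lot tibble with both ranges present.
#' @return One-row tibble: `lot_id`, `manufacturer_width`,
#'   `laboratory_width`, `width_ratio` (manufacturer / laboratory),
#'   `mean_offset` (laboratory mean - manufacturer mean).
#' @export
range_comparison <- function(lot) {
  stopifnot(is.data.frame(lot), nrow(lot) == 1L)
  if (is.na(lot$lab_mean) || is.na(lot$lab_sd)) {
    stop("lot has no laboratory-established range", call. = FALSE)
  }
  mw <- lot$manufacturer_high - lot$manufacturer_low
  lw <- 4 * lot$lab_sd
  tibble::tibble(
    lot_id = lot$lot_id,
    manufacturer_width = mw,
    laboratory_width = lw,
    width_ratio = if (lw > 0) mw / lw else NA_real_,
    mean_offset = lot$lab_mean - lot$manufacturer_mean
  )
}

#' Pooled commercial-control QC failure rate
#'
#' A QC failure is a run outside the active range (the conventional
#' out-of-range reading; a lone 1_2s warning inside the range does not
#' count).  Failures are pooled across laboratories and divided by the total
#' contributed observation time.
#'
#' @param evaluations Output of [evaluate_runs()], possibly row-bound over
#'   labs and lots.
#' @param contributed_months As in [duplicate_failure_rate()].
#' @return One-row tibble as [failure_rate()].
#' @export
control_failure_rate <- function(evaluations, contributed_months) {
  stopifnot(is.data.frame(evaluations), "in_range" %in% names(evaluations))
  months <- normalize_months(contributed_months)
  labs <- unique(evaluations$lab_id)
  missing <- setdiff(labs, names(months))
  if (length(missing)) {
    stop("no contributed months for laboratories: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  failure_rate(sum(!evaluations$in_range), sum(months[labs]))
}
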