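#' Per-laboratory study summary
#'
#' Assembles the per-laboratory IQC table of a study period: duplicate
#' analysis mean absolute percent variation with its range of calendar-month
#' means, pooled regression r-squared and Bland-Altman bias, commercial
#' control mean monthly %CV with its range, and the pooled failure rates of
#' each method per laboratory-year.  Laboratories without commercial-control
#' data keep `NA` in the control columns (rendered as an em-dash sentinel by
#' [format_study_summary()], never as 0).
#'
#' @param verdicts Output of [evaluate_pairs()] over all laboratories.
#' @param control_evaluations Optional output of [evaluate_runs()] bound
#'   over laboratories and lots (columns `lab_id`, `date`, `lot_id`,
#'   `measured_count`, `in_range`).
#' @param contributed_months Optional per-lab observation months (data frame
#'   `lab_id`, `months` or named vector); defaults to the number of distinct
#'   calendar months each laboratory reported.
#' @param k_sd Bland-Altman limits-of-agreement multiplier.
#' @return A list of class `"study_summary"`: `per_lab` (full-precision
#'   tibble), `failure_rates` (per method), `period` (date range).
#' @export
summarize_study <- function(verdicts, control_evaluations = NULL,
                            contributed_months = NULL, k_sd = 2) {
  stopifnot(is.data.frame(verdicts), nrow(verdicts) > 0)
  labs <- unique(verdicts$lab_id)
  if (is.null(contributed_months)) {
    cm <- derive_months(verdicts, control_evaluations)
  } else {
    cm <- normalize_months(contributed_months)
  }

  per_lab <- dplyr::bind_rows(lapply(labs, function(l) {
    v <- verdicts[verdicts$lab_id == l, , drop = FALSE]
    valid <- v[v$status != "invalid" & is.finite(v$pv), , drop = FALSE]
    row <- tibble::tibble(
      lab_id = l,
      instrument = if ("instrument" %in% names(v)) v$instrument[1] else "other",
      n_pairs = nrow(v),
      n_failures = sum(v$status == "fail"),
      dup_mean_abs_pv = NA_real_, dup_pv_min = NA_real_, dup_pv_max = NA_real_,
      r_squared = NA_real_, ba_bias = NA_real_, ba_sd = NA_real_,
      ctrl_product = NA_character_, n_control_runs = 0L,
      n_control_failures = NA_integer_,
      ctrl_mean_cv = NA_real_, ctrl_cv_min = NA_real_, ctrl_cv_max = NA_real_,
      months = unname(cm[l])
    )
    if (nrow(valid) >= 3L) {
      monthly <- tapply(abs(valid$pv), format(valid$date, "%Y-%m"), mean)
      row$dup_mean_abs_pv <- mean_abs_percent_variation(valid$pv)
      row$dup_pv_min <- min(monthly)
      row$dup_pv_max <- max(monthly)
      reg <- tryCatch(regression_r2(valid$day1_count, valid$day2_count),
                      error = function(e) list(r_squared = NA_real_))
      row$r_squared <- reg$r_squared
      ba <- bland_altman(valid$day1_count, valid$day2_count, k_sd = k_sd)
      row$ba_bias <- ba$bias
      row$ba_sd <- ba$sd_diff
    }
    if (!is.null(control_evaluations)) {
      ce <- control_evaluations[control_evaluations$lab_id == l, , drop = FALSE]
      if (nrow(ce)) {
        cvs <- dplyr::bind_rows(lapply(split(ce, ce$lot_id), monthly_cv))
        cvs <- cvs$cv[is.finite(cvs$cv)]
        row$n_control_runs <- nrow(ce)
        row$n_control_failures <- sum(!ce$in_range)
        if ("product" %in% names(ce)) row$ctrl_product <- ce$product[1]
        if (length(cvs)) {
          row$ctrl_mean_cv <- mean(cvs)
          row$ctrl_cv_min <- min(cvs)
          row$ctrl_cv_max <- max(cvs)
        }
      }
    }
    row
  }))

  rates <- list(duplicate_failure_rate(verdicts, cm))
  rates[[1]]$method <- "duplicate"
  if (!is.null(control_evaluations) && nrow(control_evaluations)) {
    ce <- control_evaluations
    split_by <- if ("product" %in% names(ce)) ce$product else "control"
    for (p in unique(split_by)) {
      r <- control_failure_rate(ce[split_by == p, , drop = FALSE], cm)
      r$method <- if (identical(p, "control")) "control" else p
      rates <- c(rates, list(r))
    }
  }
  structure(list(
    per_lab = per_lab,
    failure_rates = dplyr::bind_rows(rates)[, c("method", "n_failures",
                                                "lab_months",
                                                "rate_per_lab_year",
                                                "rate_per_lab_month")],
    period = range(as.Date(verdicts$date))
  ), class = "study_summary")
}

derive_months <- function(verdicts, control_evaluations) {
  tabs <- list(verdicts[, c("lab_id", "date")])
  if (!is.null(control_evaluations) && nrow(control_evaluations)) {
    tabs <- c(tabs, list(control_evaluations[, c("lab_id", "date")]))
  }
  d <- dplyr::bind_rows(tabs)
  counts <- tapply(format(as.Date(d$date), "%Y-%m"), d$lab_id,
                   function(m) length(unique(m)))
  stats::setNames(as.numeric(counts), names(counts))
}

#' Format a study summary for display
#'
#' Renders the per-lab table in report style: "mean, min-max" strings with
#' percent variation and %CV to 1 decimal, r-squared to 2 decimals, the
#' Bland-Altman bias as "bias +/- sd" to 2 decimals, and an en-dash sentinel
#' for unavailable cells.  Full precision stays in the machine-readable
#' `per_lab` table.
#'
#' @param summary A `"study_summary"` object.
#' @return Tibble of character columns.
#' @export
format_study_summary <- function(summary) {
  stopifnot(inherits(summary, "study_summary"))
  p <- summary$per_lab
  dash <- "–"
  mr <- function(m, lo, hi, digits) {
    ifelse(is.na(m), dash,
           paste0(formatC(m, format = "f", digits = digits), ", ",
                  formatC(lo, format = "f", digits = digits), dash,
                  formatC(hi, format = "f", digits = digits)))
  }
  tibble::tibble(
    lab_id = p$lab_id,
    instrument = p$instrument,
    duplicate_pv = mr(p$dup_mean_abs_pv, p$dup_pv_min, p$dup_pv_max, 1),
    control_cv = ifelse(is.na(p$ctrl_mean_cv), dash,
                        paste0(mr(p$ctrl_mean_cv, p$ctrl_cv_min,
                                  p$ctrl_cv_max, 1),
                               ifelse(is.na(p$ctrl_product), "",
                                      paste0(" (", p$ctrl_product, ")")))),
    r_squared = ifelse(is.na(p$r_squared), dash,
                       formatC(p$r_squared, format = "f", digits = 2)),
    bland_altman = ifelse(is.na(p$ba_bias), dash,
                          paste0(formatC(p$ba_bias, format = "f", digits = 2),
                                 " ± ",
                                 formatC(p$ba_sd, format = "f", digits = 2)))
  )
}

#' @export
print.study_summary <- function(x, ...) {
  cat("IQC study summary, ", format(x$period[1]), " to ", format(x$period[2]),
      " (", nrow(x$per_lab), " laboratories)\n\n", sep = "")
  print(as.data.frame(format_study_summary(x)), row.names = FALSE)
  cat("\nQC failure rates per laboratory-year:\n")
  fr <- x$failure_rates
  for (i in seq_len(nrow(fr))) {
    cat(sprintf("  %-12s %.2f (%d failures / %.0f lab-months)\n",
                fr$method[i], fr$rate_per_lab_year[i], fr$n_failures[i],
                fr$lab_months[i]))
  }
  invisible(x)
}

#' Export chart-ready data for the standard IQC plots
#'
#' Produces the plain tabular data behind each standard chart, with every
#' reference line included as a column, so the figures can be rendered by
#' any plotting tool (or checked numerically).
#'
#' @param kind One of `"regression"` (day-1 vs day-2 scatter),
#'   `"bland_altman"` (average vs difference with bias and limits of
#'   agreement per level), `"lj"` (Levey-Jennings series with mean and
#'   +/-1/2/3 sd lines), `"pv_trend"` (one lab's daily %V with 0 and
#'   +/-threshold lines), `"cross_lab_trend"` (daily cross-lab mean and SE),
#'   `"range_comparison"` (manufacturer vs laboratory range per lot).
#' @param data Verdicts (`regression`, `bland_altman`, `pv_trend`,
#'   `cross_lab_trend`), evaluations (`lj`), or a control-lot table with
#'   laboratory ranges (`range_comparison`).
#' @param lot One-row lot tibble, required for `"lj"`.
#' @param threshold,k_sd Reference-line parameters.
#' @param path Optional CSV output path.
#' @return The chart tibble (invisibly if written to `path`).
#' @export
export_chart_data <- function(kind, data, lot = NULL, threshold = 20,
                              k_sd = 2, path = NULL) {
  out <- switch(
    kind,
    regression = {
      valid <- data[data$status != "invalid", , drop = FALSE]
      tibble::tibble(lab_id = valid$lab_id, level = valid$level,
                     day1_count = valid$day1_count,
                     day2_count = valid$day2_count)
    },
    bland_altman = {
      valid <- data[data$status != "invalid", , drop = FALSE]
      dplyr::bind_rows(lapply(split(valid, valid$level), function(v) {
        ba <- bland_altman(v$day1_count, v$day2_count, k_sd = k_sd)
        tibble::tibble(level = v$level,
                       average = (v$day1_count + v$day2_count) / 2,
                       difference = v$day2_count - v$day1_count,
                       ref_bias = ba$bias, ref_loa_lower = ba$loa_lower,
                       ref_loa_upper = ba$loa_upper)
      }))
    },
    lj = {
      if (is.null(lot)) stop("`lot` is required for kind = \"lj\"", call. = FALSE)
      rng <- active_range(lot, use_provisional = TRUE)
      s <- if (is.na(rng$sd)) (rng$high - rng$low) / 4 else rng$sd
      tibble::tibble(date = as.Date(data$date), value = data$measured_count,
                     mean = rng$mean,
                     sd1_lower = rng$mean - s, sd1_upper = rng$mean + s,
                     sd2_lower = rng$mean - 2 * s, sd2_upper = rng$mean + 2 * s,
                     sd3_lower = rng$mean - 3 * s, sd3_upper = rng$mean + 3 * s,
                     range_low = rng$low, range_high = rng$high,
                     active_range = rng$source)
    },
    pv_trend = pv_trend_series(data, threshold = threshold),
    cross_lab_trend = cross_lab_trend(data),
    range_comparison = {
      dplyr::bind_rows(lapply(seq_len(nrow(data)), function(i) {
        l <- data[i, ]
        cmp <- range_comparison(l)
        tibble::tibble(lot_id = l$lot_id,
                       manufacturer_low = l$manufacturer_low,
                       manufacturer_mean = l$manufacturer_mean,
                       manufacturer_high = l$manufacturer_high,
                       laboratory_low = l$lab_mean - 2 * l$lab_sd,
                       laboratory_mean = l$lab_mean,
                       laboratory_high = l$lab_mean + 2 * l$lab_sd,
                       width_ratio = cmp$width_ratio,
                       mean_offset = cmp$mean_offset)
      }))
    },
    stop("unknown chart kind: ", kind, call. = FALSE)
  )
  if (!is.null(path)) {
    write_qc_csv(out, path)
    return(invisible(out))
  }
  out
}
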