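#' Quick Levey-Jennings chart
#'
#' Convenience ggplot of the `"lj"` chart-data export: daily control values
#' with the mean and +/-1/2/3 sd bands.  Chart data, not the rendered image,
#' is the package's tested contract; this helper is for interactive use.
#'
#' @param evaluations Output of [evaluate_runs()] for one lot.
#' @param lot The one-row lot tibble.
#' @return A ggplot object.
#' @export
plot_lj_chart <- function(evaluations, lot) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
  d <- export_chart_data("lj", evaluations, lot = lot)
  ggplot2::ggplot(d, ggplot2::aes(x = date, y = .data$value)) +
    ggplot2::geom_hline(yintercept = d$mean[1], linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = c(d$sd1_lower[1], d$sd1_upper[1]),
                        linetype = "dotted") +
    ggplot2::geom_hline(yintercept = c(d$sd2_lower[1], d$sd2_upper[1]),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(d$sd3_lower[1], d$sd3_upper[1]),
                        linetype = "longdash", colour = "red") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = NULL, y = "CD4 count (cells/µL)",
                  title = paste("Levey-Jennings chart,", lot$lot_id))
}

#' Quick percent-variation trend chart
#'
#' One laboratory's daily duplicate-analysis %V with the 0% centre line and
#' the +/-threshold acceptance lines.
#'
#' @param verdicts Output of [evaluate_pairs()] for one laboratory.
#' @param threshold Acceptance limit in percent (default 20).
#' @return A ggplot object.
#' @export
plot_pv_trend <- function(verdicts, threshold = 20) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
  d <- pv_trend_series(verdicts, threshold = threshold)
  ggplot2::ggplot(d, ggplot2::aes(x = date, y = .data$pv, colour = level)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = NULL, y = "% variation",
                  title = "Duplicate-analysis trend")
}
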