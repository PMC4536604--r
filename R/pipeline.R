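#' Run a full control stream through range establishment and LJ evaluation
#'
#' For each laboratory and lot: the first `n_establish` runs are the
#' establishment phase and are evaluated against the manufacturer's range;
#' once enough runs exist, the laboratory range (mean +/- 2 sample sd of the
#' establishment runs) becomes active and all later runs are evaluated
#' against it, with Westgard multirules applied to their z-scores.  Lots
#' that never reach `n_establish + 1` runs — e.g. short-shelf-life products —
#' stay on the manufacturer range throughout, and their z-scores remain
#' unavailable.  Rules never span lots: each lot's history starts fresh.
#'
#' @param runs Control-run tibble (`lab_id`, `date`, `lot_id`,
#'   `measured_count`).
#' @param lots Control-lot tibble (manufacturer columns as written by
#'   [simulate_control_stream()] or read by [read_control_lots_csv()]).
#' @param n_establish Runs required before the laboratory range activates
#'   (default 20, the final range; set 10 to accept provisional ranges).
#' @param rules Westgard rules, see [westgard_evaluate()].
#' @return List: `evaluations` (all runs with `z_score`, `in_range`,
#'   `active_range`, `violations`, plus `product` and `level` joined from
#'   the lot table) and `lots` (the lot table with any established
#'   `lab_mean`/`lab_sd`/`range_status`, one row per lab-lot with a range).
#' @export
analyze_control_stream <- function(runs, lots, n_establish = 20L,
                                   rules = c("1_2s", "1_3s", "2_2s", "R_4s",
                                             "4_1s", "10_x")) {
  stopifnot(is.data.frame(runs), is.data.frame(lots),
            all(c("lab_id", "date", "lot_id", "measured_count") %in% names(runs)),
            n_establish >= 10L)
  mode <- if (n_establish >= 20L) "final" else "provisional"
  evals <- list()
  est_lots <- list()
  for (key in unique(paste(runs$lab_id, runs$lot_id, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    r <- runs[runs$lab_id == parts[1] & runs$lot_id == parts[2], , drop = FALSE]
    r <- dplyr::arrange(tibble::as_tibble(r), as.Date(.data$date))
    lot <- lots[lots$lot_id == parts[2], , drop = FALSE]
    if (nrow(lot) != 1L) {
      stop("lot '", parts[2], "' not resolvable in the lot table", call. = FALSE)
    }
    lot$lab_mean <- NA_real_
    lot$lab_sd <- NA_real_
    lot$range_status <- "none"
    if (nrow(r) > n_establish) {
      est <- r[seq_len(n_establish), , drop = FALSE]
      lot <- suppressWarnings(establish_range(est, lot = lot, mode = mode))
      e1 <- evaluate_runs(est, manufacturer_only(lot), rules = rules)
      e2 <- evaluate_runs(r[-seq_len(n_establish), , drop = FALSE], lot,
                          use_provisional = TRUE, rules = rules)
      ev <- dplyr::bind_rows(e1, e2)
      est_lots <- c(est_lots, list(dplyr::mutate(lot, lab_id = parts[1],
                                                 .before = 1)))
    } else {
      ev <- evaluate_runs(r, manufacturer_only(lot), rules = rules)
    }
    ev$product <- lot$product
    ev$level <- lot$level
    evals <- c(evals, list(ev))
  }
  list(evaluations = dplyr::bind_rows(evals),
       lots = if (length(est_lots)) dplyr::bind_rows(est_lots)
              else tibble::tibble())
}

manufacturer_only <- function(lot) {
  lot$lab_mean <- NA_real_
  lot$lab_sd <- NA_real_
  lot$range_status <- "none"
  lot
}
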