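#' Westgard multirule evaluation of a Levey-Jennings z-score history
#'
#' Applies the classic six multirules to the chronological z-scores of one
#' control lot and level.  A rule is flagged on the run that completes it:
#'
#' * `1_2s` — warning: a run beyond +/-2 sd (strictly).
#' * `1_3s` — a run beyond +/-3 sd.
#' * `2_2s` — two consecutive runs beyond 2 sd on the same side.
#' * `R_4s` — two adjacent runs on opposite sides, each beyond 2 sd (a
#'   within-pair range of at least 4 sd).
#' * `4_1s` — four consecutive runs beyond 1 sd on the same side.
#' * `10_x` — ten consecutive runs on the same side of the mean (a run
#'   exactly on the mean breaks the streak).
#'
#' Rules never span lots: evaluate each lot's history separately.
#'
#' @param z Numeric vector of z-scores in chronological order.
#' @param rules Character vector of rules to apply (subset of the six).
#' @return A list, one character vector of violated rule ids per run
#'   (possibly empty).
#' @export
westgard_evaluate <- function(z,
                              rules = c("1_2s", "1_3s", "2_2s", "R_4s",
                                        "4_1s", "10_x")) {
  if (!all(is.finite(z))) {
    stop("z-scores unavailable: establish a laboratory range first",
         call. = FALSE)
  }
  known <- c("1_2s", "1_3s", "2_2s", "R_4s", "4_1s", "10_x")
  bad <- setdiff(rules, known)
  if (length(bad)) stop("unknown Westgard rule: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  n <- length(z)
  out <- vector("list", n)
  if (n == 0L) return(out)
  side <- sign(z)
  for (i in seq_len(n)) {
    v <- character()
    if ("1_2s" %in% rules && abs(z[i]) > 2) v <- c(v, "1_2s")
    if ("1_3s" %in% rules && abs(z[i]) > 3) v <- c(v, "1_3s")
    if ("2_2s" %in% rules && i >= 2 &&
        ((z[i] > 2 && z[i - 1] > 2) || (z[i] < -2 && z[i - 1] < -2))) {
      v <- c(v, "2_2s")
    }
    if ("R_4s" %in% rules && i >= 2 &&
        ((z[i] > 2 && z[i - 1] < -2) || (z[i] < -2 && z[i - 1] > 2))) {
      v <- c(v, "R_4s")
    }
    if ("4_1s" %in% rules && i >= 4 &&
        (all(z[(i - 3):i] > 1) || all(z[(i - 3):i] < -1))) {
      v <- c(v, "4_1s")
    }
    if ("10_x" %in% rules && i >= 10 &&
        (all(side[(i - 9):i] == 1) || all(side[(i - 9):i] == -1))) {
      v <- c(v, "10_x")
    }
    out[[i]] <- v
  }
  out
}

#' Westgard rejections in a violation set
#'
#' Helper separating the 1_2s warning from the rejection rules: a run is a
#' multirule rejection when any rule other than 1_2s fires.
#'
#' @param violations List of character vectors (from [westgard_evaluate()])
#'   or a character vector of semicolon-joined ids.
#' @return Logical vector, `TRUE` where the run is rejected.
#' @export
westgard_rejected <- function(violations) {
  if (is.character(violations)) violations <- strsplit(violations, ";", fixed = TRUE)
  vapply(violations, function(v) any(setdiff(v, c("1_2s", "")) != ""), logical(1))
}
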