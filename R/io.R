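#' Read a duplicate-pair QC log
#'
#' CSV schema (header required): `lab_id, instrument, date, level,
#' day1_count, day2_count`, with ISO-8601 dates and level `low`/`normal`.
#' A missing required column is a hard error; malformed rows are collected
#' into a rejects table with their line numbers and reasons, never silently
#' dropped.
#'
#' @param path CSV file path.
#' @param count_unit `"cells/uL"` (default) or `"cells/mL"`; counts in
#'   cells/mL are divided by 1000 on read.
#' @return List: `records` (typed tibble) and `rejects` (tibble `line`,
#'   `reason`).
#' @export
read_duplicate_csv <- function(path, count_unit = c("cells/uL", "cells/mL")) {
  count_unit <- match.arg(count_unit)
  raw <- read_raw_csv(path, c("lab_id", "date", "level",
                              "day1_count", "day2_count"))
  if (!"instrument" %in% names(raw)) raw$instrument <- "other"
  parsed <- parse_rows(raw, list(
    date = parse_iso_date,
    level = function(x) parse_enum(x, c("low", "normal")),
    day1_count = parse_number_field,
    day2_count = parse_number_field
  ))
  rec <- parsed$records
  if (count_unit == "cells/mL" && nrow(rec)) {
    rec$day1_count <- rec$day1_count / 1000
    rec$day2_count <- rec$day2_count / 1000
  }
  rec <- rec[, c("lab_id", "instrument", "date", "level",
                 "day1_count", "day2_count")]
  list(records = rec, rejects = parsed$rejects)
}

#' Read a control-run QC log
#'
#' CSV schema: `lab_id, date, lot_id, measured_count`.
#'
#' @inheritParams read_duplicate_csv
#' @return List: `records`, `rejects`.
#' @export
read_control_runs_csv <- function(path, count_unit = c("cells/uL", "cells/mL")) {
  count_unit <- match.arg(count_unit)
  raw <- read_raw_csv(path, c("lab_id", "date", "lot_id", "measured_count"))
  parsed <- parse_rows(raw, list(date = parse_iso_date,
                                 measured_count = parse_number_field))
  rec <- parsed$records
  if (count_unit == "cells/mL" && nrow(rec)) {
    rec$measured_count <- rec$measured_count / 1000
  }
  rec <- rec[, c("lab_id", "date", "lot_id", "measured_count")]
  list(records = rec, rejects = parsed$rejects)
}

#' Read a control-lot table
#'
#' CSV schema: `lot_id, product, level, manufacturer_mean, manufacturer_low,
#' manufacturer_high` with optional `expiry`, `lab_mean`, `lab_sd`,
#' `range_status`.
#'
#' @param path CSV file path.
#' @return List: `records`, `rejects`.
#' @export
read_control_lots_csv <- function(path) {
  raw <- read_raw_csv(path, c("lot_id", "product", "level",
                              "manufacturer_mean", "manufacturer_low",
                              "manufacturer_high"))
  if (!"lab_mean" %in% names(raw)) raw$lab_mean <- NA_character_
  if (!"lab_sd" %in% names(raw)) raw$lab_sd <- NA_character_
  if (!"range_status" %in% names(raw)) raw$range_status <- "none"
  parsed <- parse_rows(raw, list(
    level = function(x) parse_enum(x, c("low", "normal")),
    manufacturer_mean = parse_number_field,
    manufacturer_low = parse_number_field,
    manufacturer_high = parse_number_field,
    lab_mean = parse_optional_number,
    lab_sd = parse_optional_number,
    range_status = function(x) parse_enum(x, c("none", "provisional", "final"))
  ))
  list(records = parsed$records, rejects = parsed$rejects)
}

#' Write a QC table as CSV
#'
#' Comma-separated, UTF-8, ISO-8601 dates, `.` decimal separator, header
#' included; list columns (e.g. raw violation sets) are semicolon-joined.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_csv <- function(x, path) {
  x <- as.data.frame(x)
  for (nm in names(x)) {
    if (is.list(x[[nm]])) {
      x[[nm]] <- vapply(x[[nm]], paste, "", collapse = ";")
    }
  }
  readr::write_csv(x, path, na = "")
  invisible(path)
}

# -- internal parsing helpers -------------------------------------------------

read_raw_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw
}

# apply per-column parsers; a row failing any parser becomes a reject with
# its 1-based data line number (header = line 1)
parse_rows <- function(raw, parsers) {
  n <- nrow(raw)
  reason <- rep(NA_character_, n)
  parsed <- raw
  for (nm in names(parsers)) {
    res <- parsers[[nm]](raw[[nm]])
    bad <- res$bad & is.na(reason)
    reason[bad] <- paste0(nm, ": ", res$why[bad])
    parsed[[nm]] <- res$value
  }
  keep <- is.na(reason)
  rejects <- tibble::tibble(line = which(!keep) + 1L, reason = reason[!keep])
  list(records = tibble::as_tibble(parsed[keep, , drop = FALSE]),
       rejects = rejects)
}

parse_iso_date <- function(x) {
  v <- as.Date(x, format = "%Y-%m-%d")
  bad <- is.na(v)
  list(value = v, bad = bad,
       why = ifelse(bad, paste0("not an ISO-8601 date ('", x, "')"), NA))
}

parse_number_field <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v)
  list(value = v, bad = bad,
       why = ifelse(bad, paste0("not a number ('", x, "')"), NA))
}

parse_optional_number <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) & !is.na(x) & x != ""
  list(value = v, bad = bad,
       why = ifelse(bad, paste0("not a number ('", x, "')"), NA))
}

parse_enum <- function(x, allowed) {
  bad <- !(x %in% allowed)
  list(value = x, bad = bad,
       why = ifelse(bad, paste0("must be one of ",
                                paste(allowed, collapse = "/"),
                                " ('", x, "')"), NA))
}
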