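## Gas species measured by automated head-chamber systems, in g/d.
GAS_NAMES <- c("CH4", "CO2", "O2", "H2")

#' Default column mapping for visit-record exports
#'
#' Automated head-chamber exports vary between sites; the reader takes a
#' mapping from internal field names to file column names so any dialect can
#' be ingested. This is the default dialect. `animal_id_fallback` is used
#' when the primary animal-identifier column is absent from the file.
#'
#' @return Named list mapping internal fields to CSV column names.
#' @export
#' @examples
#' default_visit_columns()$start_time
default_visit_columns <- function() {
  list(
    animal_id = "RFID",
    animal_id_fallback = "AnimalName",
    unit_id = "FeederID",
    start_time = "StartTime",
    end_time = "EndTime",
    good_duration = "GoodDataDuration",
    CH4 = "CH4GramsPerDay",
    CO2 = "CO2GramsPerDay",
    O2 = "O2GramsPerDay",
    H2 = "H2GramsPerDay"
  )
}

#' Default column mapping for feed-drop event ("feedtimes") exports
#'
#' @return Named list mapping internal fields to CSV column names.
#' @export
default_feedtime_columns <- function() {
  list(
    animal_id = "RFID",
    animal_id_fallback = "AnimalName",
    unit_id = "FeederID",
    time = "Time",
    drops = "Drops"
  )
}

## Timestamps are farm-local "naive" times; they are stored as POSIXct in UTC
## purely as a carrier (no timezone conversion is ever applied).
parse_timestamp <- function(x) {
  x <- trimws(as.character(x))
  out <- as.POSIXct(rep(NA_character_, length(x)), tz = "UTC")
  formats <- c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M",
               "%m/%d/%Y %H:%M:%S", "%m/%d/%Y %H:%M")
  for (f in formats) {
    idx <- which(is.na(out) & !is.na(x) & x != "")
    if (length(idx) == 0) break
    out[idx] <- as.POSIXct(strptime(x[idx], f, tz = "UTC"))
  }
  out
}

## Good-data duration appears in the wild either as "HH:MM:SS" text or as
## decimal minutes; normalize to decimal minutes.
parse_duration_min <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  is_hms <- grepl("^\\d{1,3}:\\d{2}:\\d{2}(\\.\\d+)?$", x)
  if (any(is_hms, na.rm = TRUE)) {
    idx <- which(is_hms)
    parts <- strsplit(x[idx], ":", fixed = TRUE)
    out[idx] <- vapply(parts, function(p) {
      p <- as.numeric(p)
      p[1] * 60 + p[2] + p[3] / 60
    }, numeric(1))
  }
  plain <- which(!is_hms | is.na(is_hms))
  out[plain] <- suppressWarnings(as.numeric(x[plain]))
  out
}

## Gas production of exactly 0, negative, or blank is treated as missing for
## that gas: the preprocessing system emits rows whose gas estimate failed.
parse_gas <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  v[!is.finite(v) | v <= 0] <- NA_real_
  v
}

#' Canonicalize animal identifiers
#'
#' Trims whitespace, strips leading zeros from all-digit identifiers (RFID
#' transponders are commonly zero-padded to 15 digits), and, when a roster is
#' supplied, maps canonicalized RFIDs to farm identifiers. Unmapped
#' identifiers pass through canonicalized. The function is idempotent.
#'
#' @param raw Character vector of raw identifiers.
#' @param roster Optional roster data frame with columns `rfid` and
#'   `farm_id` (see [read_roster()]).
#' @return Character vector of canonical identifiers.
#' @export
#' @examples
#' canonical_id("0000982123")
#' canonical_id("982123", roster = data.frame(rfid = "982123", farm_id = "Cow24"))
canonical_id <- function(raw, roster = NULL) {
  x <- trimws(as.character(raw))
  if (length(x) > 0 && any(is.na(x) | x == "")) {
    rlang::abort("invalid animal identifier: empty or missing after trimming")
  }
  digits <- grepl("^[0-9]+$", x)
  x[digits] <- sub("^0+(?=[0-9])", "", x[digits], perl = TRUE)
  if (!is.null(roster) && nrow(roster) > 0) {
    key <- trimws(as.character(roster$rfid))
    kd <- grepl("^[0-9]+$", key)
    key[kd] <- sub("^0+(?=[0-9])", "", key[kd], perl = TRUE)
    hit <- match(x, key)
    x[!is.na(hit)] <- as.character(roster$farm_id)[hit[!is.na(hit)]]
  }
  x
}

#' Read an animal roster
#'
#' A roster maps RFID transponder codes to farm identifiers and defines the
#' set of animals expected on trial (used for zero-filling and non-visitor
#' detection).
#'
#' @param path CSV file with columns `RFID` and `FarmID` (case-insensitive;
#'   the first two columns are used if those names are absent).
#' @return Tibble with columns `rfid` (canonicalized) and `farm_id`.
#' @export
read_roster <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE, show_col_types = FALSE)
  nm <- tolower(names(df))
  ri <- match("rfid", nm)
  fi <- match("farmid", nm)
  if (is.na(ri)) ri <- 1L
  if (is.na(fi)) fi <- if (ncol(df) >= 2) 2L else 1L
  out <- tibble::tibble(
    rfid = canonical_id(df[[ri]]),
    farm_id = trimws(as.character(df[[fi]]))
  )
  if (anyDuplicated(out$rfid)) {
    rlang::abort("roster RFIDs are not unique after canonicalization")
  }
  out
}

resolve_columns <- function(nms, column_map, file, mandatory) {
  aid <- column_map$animal_id
  if (!aid %in% nms && !is.null(column_map$animal_id_fallback) &&
      column_map$animal_id_fallback %in% nms) {
    column_map$animal_id <- column_map$animal_id_fallback
  }
  for (f in mandatory) {
    col <- column_map[[f]]
    if (is.null(col) || !col %in% nms) {
      rlang::abort(sprintf(
        "missing mandatory column '%s' (field '%s') in %s",
        if (is.null(col)) f else col, f, file
      ))
    }
  }
  column_map
}

new_ingest_report <- function(rows_read, rows_kept, reasons) {
  list(
    rows_read = rows_read,
    rows_kept = rows_kept,
    rows_dropped = rows_read - rows_kept,
    reasons = reasons
  )
}

#' Retrieve the ingestion report attached to a read table
#'
#' Both readers drop malformed rows rather than aborting (field data are
#' dirty; reports must still render) and attach an audit trail:
#' `rows_read`, `rows_kept`, `rows_dropped` and a named count of drop
#' reasons. `rows_kept + rows_dropped == rows_read` always holds.
#'
#' @param x A table returned by [read_visits()] or [read_feedtimes()].
#' @return A list with elements `rows_read`, `rows_kept`, `rows_dropped`,
#'   `reasons`.
#' @export
ingest_report <- function(x) {
  rep <- attr(x, "ingest", exact = TRUE)
  if (is.null(rep)) rlang::abort("no ingestion report attached to this object")
  rep
}

#' Read preprocessed visit records
#'
#' Reads one row per preprocessed visit: animal, unit, start/end timestamp,
#' usable ("good data") measurement duration in minutes, and per-gas
#' production rates in g/d. Rows with unparseable timestamps, inverted
#' intervals, or durations exceeding the visit interval are dropped and
#' counted in the ingestion report ([ingest_report()]).
#'
#' Timestamps are parsed as naive farm-local time; a gas value of 0 or blank
#' is treated as missing for that gas.
#'
#' @param path CSV file of visit records.
#' @param column_map Mapping from internal fields to file columns; see
#'   [default_visit_columns()].
#' @param roster Optional roster for identifier reconciliation.
#' @return Tibble with columns `animal_id`, `unit_id`, `start_time`,
#'   `end_time`, `good_duration_min`, `CH4`, `CO2`, `O2`, `H2`, with the
#'   ingestion report attached as attribute `"ingest"`.
#' @export
read_visits <- function(path, column_map = default_visit_columns(),
                        roster = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE, show_col_types = FALSE)
  n <- nrow(df)
  if (n == 0) {
    rlang::warn(sprintf("no data rows in %s", path))
    out <- empty_visits()
    attr(out, "ingest") <- new_ingest_report(0L, 0L, integer(0))
    return(out)
  }
  cm <- resolve_columns(names(df), column_map, path,
                        mandatory = c("animal_id", "unit_id", "start_time",
                                      "end_time", "good_duration"))
  start_time <- parse_timestamp(df[[cm$start_time]])
  end_time <- parse_timestamp(df[[cm$end_time]])
  dur <- parse_duration_min(df[[cm$good_duration]])
  raw_id <- trimws(as.character(df[[cm$animal_id]]))

  reason <- rep(NA_character_, n)
  elapsed_min <- as.numeric(difftime(end_time, start_time, units = "mins"))
  bad_dur <- is.na(dur) | dur < 0 | dur > elapsed_min + 1e-6
  reason[bad_dur] <- "duration"
  reason[!is.na(start_time) & !is.na(end_time) & end_time < start_time] <- "interval"
  reason[is.na(raw_id) | raw_id == ""] <- "id"
  reason[is.na(start_time) | is.na(end_time)] <- "timestamp"

  keep <- is.na(reason)
  out <- tibble::tibble(
    animal_id = canonical_id(raw_id[keep], roster),
    unit_id = trimws(as.character(df[[cm$unit_id]]))[keep],
    start_time = start_time[keep],
    end_time = end_time[keep],
    good_duration_min = dur[keep]
  )
  for (g in GAS_NAMES) {
    col <- cm[[g]]
    out[[g]] <- if (!is.null(col) && col %in% names(df)) {
      parse_gas(df[[col]])[keep]
    } else NA_real_
  }
  attr(out, "ingest") <- new_ingest_report(
    n, sum(keep), table_int(reason[!keep])
  )
  out
}

#' Read feed-drop events (the "feedtimes" file)
#'
#' One row per pellet-drop event: unit, animal, timestamp and number of
#' drops dispensed. Rows with unparseable timestamps or with missing,
#' negative or non-integer drop counts are dropped and counted.
#'
#' @inheritParams read_visits
#' @param column_map See [default_feedtime_columns()].
#' @return Tibble with columns `animal_id`, `unit_id`, `time`, `drops`, with
#'   attribute `"ingest"`.
#' @export
read_feedtimes <- function(path, column_map = default_feedtime_columns(),
                           roster = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE, show_col_types = FALSE)
  n <- nrow(df)
  if (n == 0) {
    rlang::warn(sprintf("no data rows in %s", path))
    out <- empty_feedtimes()
    attr(out, "ingest") <- new_ingest_report(0L, 0L, integer(0))
    return(out)
  }
  cm <- resolve_columns(names(df), column_map, path,
                        mandatory = c("animal_id", "unit_id", "time", "drops"))
  tm <- parse_timestamp(df[[cm$time]])
  drops <- suppressWarnings(as.numeric(df[[cm$drops]]))
  raw_id <- trimws(as.character(df[[cm$animal_id]]))

  reason <- rep(NA_character_, n)
  reason[is.na(drops) | drops < 0 | drops != round(drops)] <- "drops"
  reason[is.na(raw_id) | raw_id == ""] <- "id"
  reason[is.na(tm)] <- "timestamp"

  keep <- is.na(reason)
  out <- tibble::tibble(
    animal_id = canonical_id(raw_id[keep], roster),
    unit_id = trimws(as.character(df[[cm$unit_id]]))[keep],
    time = tm[keep],
    drops = as.integer(drops[keep])
  )
  attr(out, "ingest") <- new_ingest_report(
    n, sum(keep), table_int(reason[!keep])
  )
  out
}

table_int <- function(x) {
  if (length(x) == 0) return(integer(0))
  tab <- table(x)
  stats::setNames(as.integer(tab), names(tab))
}

empty_visits <- function() {
  out <- tibble::tibble(
    animal_id = character(0), unit_id = character(0),
    start_time = as.POSIXct(character(0), tz = "UTC"),
    end_time = as.POSIXct(character(0), tz = "UTC"),
    good_duration_min = numeric(0)
  )
  for (g in GAS_NAMES) out[[g]] <- numeric(0)
  out
}

empty_feedtimes <- function() {
  tibble::tibble(
    animal_id = character(0), unit_id = character(0),
    time = as.POSIXct(character(0), tz = "UTC"),
    drops = integer(0)
  )
}

#' Write a result table to disk
#'
#' CSV output round-trips bit-stably through [readr::read_csv()]. XLSX
#' output is not available in this installation (no spreadsheet writer is
#' present); requesting it raises an informative error so callers can fall
#' back to CSV, which every spreadsheet application opens.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @param format `"csv"` (default) or `"xlsx"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = c("csv", "xlsx")) {
  format <- match.arg(format)
  if (format == "xlsx") {
    rlang::abort(paste0(
      "XLSX output requires a spreadsheet writer, which is not installed; ",
      "use format = 'csv' (CSV opens in any spreadsheet application)."
    ))
  }
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}

#' Define a study window
#'
#' @param start_date,end_date Dates (or strings coercible to dates) of the
#'   first and last trial day, inclusive.
#' @return A list with `start_date`, `end_date` and `n_days`
#'   (`end - start + 1`), class `"study_window"`.
#' @export
#' @examples
#' study_window("2024-01-15", "2024-02-29")$n_days
study_window <- function(start_date, end_date) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date)) {
    rlang::abort("study window dates must be parseable as dates")
  }
  if (end_date < start_date) {
    rlang::abort("study end_date must be >= start_date")
  }
  structure(
    list(start_date = start_date, end_date = end_date,
         n_days = as.integer(end_date - start_date) + 1L),
    class = "study_window"
  )
}

#' @export
print.study_window <- function(x, ...) {
  cat(sprintf("<study_window> %s to %s (%d days)\n",
              format(x$start_date), format(x$end_date), x$n_days))
  invisible(x)
}

## Infer a study window from data when the caller did not provide one.
infer_study <- function(visits = NULL, events = NULL) {
  times <- c(
    if (!is.null(visits) && nrow(visits) > 0) visits$start_time,
    if (!is.null(events) && nrow(events) > 0) events$time
  )
  if (length(times) == 0) rlang::abort("cannot infer a study window from empty data")
  d <- as.Date(times, tz = "UTC")
  study_window(min(d), max(d))
}
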