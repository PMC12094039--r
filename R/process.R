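#' Record-sufficiency parameters for gas-phenotype aggregation
#'
#' Three thresholds govern which records and animal-days enter the daily and
#' weekly phenotypes: `min_time`, the minimum usable visit duration in
#' minutes (a valid spot measurement needs at least 2 min of head-in-chamber
#' time, so values below 2 are rejected); `param1`, the minimum number of
#' records per animal-day for a daily average; and `param2`, the minimum
#' number of days with records per animal-week for a weekly average.
#' `outlier_k` is the half-width, in SDs, of the per-gas outlier band.
#'
#' @param param1 Minimum records per animal-day (integer >= 1).
#' @param param2 Minimum days with records per animal-week (integer >= 1).
#' @param min_time Minimum visit duration in minutes (>= 2).
#' @param outlier_k Outlier band half-width in SD units (> 0), default 3.
#' @return A validated list of class `"process_params"`.
#' @export
#' @examples
#' process_params(param1 = 2, param2 = 4, min_time = 2)
process_params <- function(param1 = 1L, param2 = 1L, min_time = 2,
                           outlier_k = 3) {
  param1 <- as.integer(param1)
  param2 <- as.integer(param2)
  if (is.na(param1) || param1 < 1) rlang::abort("param1 must be an integer >= 1")
  if (is.na(param2) || param2 < 1) rlang::abort("param2 must be an integer >= 1")
  if (!is.finite(min_time) || min_time < 2) {
    rlang::abort("min_time must be >= 2 minutes (shorter visits are not valid measurements)")
  }
  if (!is.finite(outlier_k) || outlier_k <= 0) {
    rlang::abort("outlier_k must be > 0")
  }
  structure(list(param1 = param1, param2 = param2,
                 min_time = as.numeric(min_time),
                 outlier_k = as.numeric(outlier_k)),
            class = "process_params")
}

#' @export
print.process_params <- function(x, ...) {
  cat(sprintf("<process_params> param1=%d, param2=%d, min_time=%g min, outlier_k=%g\n",
              x$param1, x$param2, x$min_time, x$outlier_k))
  invisible(x)
}

#' Keep records meeting the minimum visit duration
#'
#' The boundary is inclusive: a record whose usable duration equals
#' `min_time` is retained.
#'
#' @param records Visit-record tibble (see [read_visits()]).
#' @param min_time Minimum usable duration in minutes (>= 2).
#' @return The retained records.
#' @export
filter_min_time <- function(records, min_time = 2) {
  if (!is.finite(min_time) || min_time < 2) {
    rlang::abort("min_time must be >= 2 minutes (shorter visits are not valid measurements)")
  }
  records[records$good_duration_min >= min_time, , drop = FALSE]
}

#' Mask per-gas outliers at mean +/- k*SD
#'
#' For each gas independently, the mean and sample SD are computed once over
#' all non-missing values; values outside `mean +/- outlier_k * SD` are set
#' missing. Statistics are not recomputed after masking (a single removal
#' step, not an iterative trim), and they pool all animals. A record left
#' with no gas values at all is dropped. With fewer than two non-missing
#' values the SD is undefined and nothing is masked for that gas.
#'
#' @param records Visit-record tibble, already duration-filtered.
#' @param outlier_k Band half-width in SD units, default 3.
#' @return The records with outlying gas values set to `NA`; counts of
#'   masked values per gas are attached as attribute `"masked"`.
#' @export
remove_gas_outliers <- function(records, outlier_k = 3) {
  masked <- stats::setNames(integer(4), GAS_NAMES)
  if (nrow(records) > 0) {
    for (g in GAS_NAMES) {
      v <- records[[g]]
      ok <- !is.na(v)
      if (sum(ok) < 2) next
      m <- mean(v[ok])
      s <- stats::sd(v[ok])
      out <- ok & (v < m - outlier_k * s | v > m + outlier_k * s)
      masked[[g]] <- sum(out)
      records[[g]][out] <- NA_real_
    }
    all_missing <- rowSums(!is.na(as.matrix(records[GAS_NAMES]))) == 0
    records <- records[!all_missing, , drop = FALSE]
  }
  attr(records, "masked") <- masked
  records
}

#' Duration-weighted daily gas averages per animal
#'
#' Records are grouped by animal and the calendar date of the visit start
#' (farm-local time). Per gas, the daily mean is weighted by each record's
#' usable duration, over records where that gas is non-missing; a gas with
#' no valid values that day is missing, never 0. An animal-day is emitted
#' only when its record count reaches `param1`.
#'
#' @param records Filtered visit-record tibble.
#' @param param1 Minimum records per animal-day.
#' @return Tibble with `animal_id`, `date`, `n_records`, `total_minutes`,
#'   and one duration-weighted mean column per gas, ordered by animal then
#'   date.
#' @export
#' @examples
#' # durations 2 and 4 min with CH4 300 and 360 average to (2*300+4*360)/6 = 340
daily_averages <- function(records, param1 = 1L) {
  if (nrow(records) == 0) return(empty_daily())
  records$date <- as.Date(records$start_time, tz = "UTC")
  out <- records |>
    dplyr::group_by(.data$animal_id, .data$date) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      total_minutes = sum(.data$good_duration_min),
      dplyr::across(dplyr::all_of(GAS_NAMES),
                    ~ weighted_gas_mean(.x, .data$good_duration_min)),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_records >= param1) |>
    dplyr::arrange(.data$animal_id, .data$date)
  out
}

weighted_gas_mean <- function(x, w) {
  ok <- !is.na(x)
  if (!any(ok)) return(NA_real_)
  sum(x[ok] * w[ok]) / sum(w[ok])
}

empty_daily <- function() {
  out <- tibble::tibble(animal_id = character(0),
                        date = as.Date(character(0)),
                        n_records = integer(0), total_minutes = numeric(0))
  for (g in GAS_NAMES) out[[g]] <- numeric(0)
  out
}

empty_weekly <- function() {
  out <- tibble::tibble(animal_id = character(0), week_index = integer(0),
                        n_days = integer(0), n_records = integer(0),
                        total_minutes = numeric(0))
  for (g in GAS_NAMES) out[[g]] <- numeric(0)
  out
}

#' Minute-weighted weekly gas averages per animal
#'
#' Study weeks are consecutive 7-day blocks anchored at the study start
#' date (`week_index = floor((date - start)/7) + 1`), not ISO calendar
#' weeks: a trial of 46 consecutive days spans study-weeks 1-7. Per gas,
#' the weekly mean weights each contributing daily mean by that day's total
#' visit-record minutes. An animal-week is emitted only when it has at
#' least `param2` distinct days with records.
#'
#' @param daily Output of [daily_averages()].
#' @param param2 Minimum days with records per animal-week.
#' @param study A [study_window()] anchoring week 1.
#' @return Tibble with `animal_id`, `week_index`, `n_days`, `n_records`,
#'   `total_minutes`, and one minute-weighted mean column per gas.
#' @export
weekly_averages <- function(daily, param2 = 1L, study) {
  if (nrow(daily) == 0) return(empty_weekly())
  daily$week_index <- as.integer(
    floor(as.numeric(daily$date - study$start_date) / 7)) + 1L
  daily |>
    dplyr::group_by(.data$animal_id, .data$week_index) |>
    dplyr::summarise(
      n_days = dplyr::n_distinct(.data$date),
      n_records = sum(.data$n_records),
      dplyr::across(dplyr::all_of(GAS_NAMES),
                    ~ weighted_gas_mean(.x, .data$total_minutes)),
      total_minutes = sum(.data$total_minutes),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_days >= param2) |>
    dplyr::select(dplyr::all_of(c("animal_id", "week_index", "n_days",
                                  "n_records", "total_minutes", GAS_NAMES))) |>
    dplyr::arrange(.data$animal_id, .data$week_index)
}

#' Process visit records into daily and weekly gas phenotypes
#'
#' The full engine, composed of four stages in the order the method
#' prescribes: (1) keep records with usable duration >= `min_time`; (2)
#' single-pass per-gas outlier masking at mean +/- `outlier_k`*SD; (3)
#' duration-weighted daily averages for animal-days with >= `param1`
#' records; (4) minute-weighted weekly averages for animal-weeks with >=
#' `param2` days with records.
#'
#' @param records Visit-record tibble.
#' @param params A [process_params()].
#' @param study A [study_window()]; inferred from the data when omitted.
#' @return A list of class `"gf_processed"` with elements `daily`,
#'   `weekly`, and `counts` (records in, after duration filter, after
#'   outlier masking, daily rows, weekly rows — the audit trail behind any
#'   "retained x%" statement).
#' @export
#' @examples
#' trial <- simulate_trial(sim_config(n_animals = 6, n_days = 14, seed = 7))
#' res <- process_records(trial$visits, process_params(2, 4, 2))
#' head(res$daily)
process_records <- function(records, params = process_params(), study = NULL) {
  stopifnot(inherits(params, "process_params"))
  if (is.null(study)) {
    study <- if (nrow(records) > 0) infer_study(visits = records) else NULL
  }
  kept_time <- filter_min_time(records, params$min_time)
  kept_out <- remove_gas_outliers(kept_time, params$outlier_k)
  daily <- daily_averages(kept_out, params$param1)
  weekly <- if (is.null(study)) empty_weekly() else {
    weekly_averages(daily, params$param2, study)
  }
  structure(list(
    daily = daily, weekly = weekly,
    counts = list(
      rows_in = nrow(records),
      after_min_time = nrow(kept_time),
      after_outliers = nrow(kept_out),
      masked_values = attr(kept_out, "masked"),
      daily_rows = nrow(daily),
      weekly_rows = nrow(weekly)
    )
  ), class = "gf_processed")
}

#' @export
print.gf_processed <- function(x, ...) {
  cn <- x$counts
  cat(sprintf(
    "<gf_processed> %d records -> %d (duration) -> %d (outliers) -> %d daily rows -> %d weekly rows\n",
    cn$rows_in, cn$after_min_time, cn$after_outliers, cn$daily_rows, cn$weekly_rows))
  invisible(x)
}

#' Summary statistics for a set of gas values
#'
#' Reports n, mean, sample SD (n-1 denominator; 0 for a single value so
#' report tables stay total), CV = 100*SD/mean (missing when the mean is
#' not positive), minimum and maximum.
#'
#' @param values Numeric vector of gas production values; missing values
#'   are ignored.
#' @param gas Optional gas label carried into the output.
#' @return One-row tibble `gas`, `n`, `mean`, `sd`, `cv`, `min`, `max`.
#' @export
#' @examples
#' summarize_gas(c(10, 20)) # mean 15, sd 7.07, cv 47.1%
summarize_gas <- function(values, gas = NA_character_) {
  values <- values[!is.na(values)]
  if (length(values) == 0) rlang::abort("summarize_gas needs at least one value")
  m <- mean(values)
  s <- if (length(values) < 2) 0 else stats::sd(values)
  tibble::tibble(
    gas = gas, n = length(values), mean = m, sd = s,
    cv = if (m > 0) 100 * s / m else NA_real_,
    min = min(values), max = max(values)
  )
}

#' Sweep the filtering parameters over a grid
#'
#' Runs [process_records()] for every combination of `param1`, `param2` and
#' `min_time` and tabulates, for one gas, the retained daily/weekly record
#' and animal counts and the mean +/- SD of the daily and weekly averages —
#' the layout of a record-retention sensitivity table. Combinations with no
#' weekly rows report missing means.
#'
#' @param records Visit-record tibble.
#' @param param1_set,param2_set,min_time_set Parameter values to cross.
#' @param study A [study_window()]; inferred when omitted.
#' @param gas Gas to summarize, default `"CH4"`.
#' @param outlier_k Outlier band half-width, default 3.
#' @return Tibble with one row per combination: `param1`, `param2`,
#'   `min_time`, `n_daily_records`, `n_animals_daily`, `daily_mean`,
#'   `daily_sd`, `n_weekly_records`, `n_animals_weekly`, `weekly_mean`,
#'   `weekly_sd`.
#' @export
param_grid <- function(records, param1_set = 1:3, param2_set = 3:7,
                       min_time_set = 2:3, study = NULL, gas = "CH4",
                       outlier_k = 3) {
  stopifnot(length(param1_set) > 0, length(param2_set) > 0,
            length(min_time_set) > 0, gas %in% GAS_NAMES)
  if (is.null(study) && nrow(records) > 0) study <- infer_study(visits = records)
  combos <- expand.grid(param2 = as.integer(param2_set),
                        param1 = as.integer(param1_set),
                        min_time = as.numeric(min_time_set))
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    p1 <- combos$param1[i]; p2 <- combos$param2[i]; mt <- combos$min_time[i]
    ## weekly thresholds do not affect the daily table, so compute daily
    ## once per (param1, min_time) would be possible; kept simple and exact.
    res <- process_records(records,
                           process_params(p1, p2, mt, outlier_k), study)
    dvals <- res$daily[[gas]]
    wvals <- res$weekly[[gas]]
    dvals <- dvals[!is.na(dvals)]
    wvals <- wvals[!is.na(wvals)]
    tibble::tibble(
      param1 = p1, param2 = p2, min_time = mt,
      n_daily_records = nrow(res$daily),
      n_animals_daily = dplyr::n_distinct(res$daily$animal_id),
      daily_mean = if (length(dvals)) mean(dvals) else NA_real_,
      daily_sd = if (length(dvals) > 1) stats::sd(dvals) else NA_real_,
      n_weekly_records = nrow(res$weekly),
      n_animals_weekly = dplyr::n_distinct(res$weekly$animal_id),
      weekly_mean = if (length(wvals)) mean(wvals) else NA_real_,
      weekly_sd = if (length(wvals) > 1) stats::sd(wvals) else NA_real_
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$min_time, .data$param1, .data$param2)
}

#' Correlation between a filter parameter and a grid column
#'
#' Pearson correlation across the rows of a [param_grid()] table, e.g.
#' between `param1` and the number of retained daily records. Undefined
#' correlations (fewer than 3 finite pairs, or zero variance in either
#' variable) are reported as missing.
#'
#' @param grid A [param_grid()] table.
#' @param x Name of the parameter column (`"param1"`, `"param2"`,
#'   `"min_time"`).
#' @param y Name of the outcome column.
#' @return A single numeric correlation, or `NA` when undefined.
#' @export
grid_correlation <- function(grid, x, y) {
  stopifnot(x %in% names(grid), y %in% names(grid))
  xv <- as.numeric(grid[[x]])
  yv <- as.numeric(grid[[y]])
  ok <- is.finite(xv) & is.finite(yv)
  if (sum(ok) < 3) return(NA_real_)
  if (stats::sd(xv[ok]) == 0 || stats::sd(yv[ok]) == 0) return(NA_real_)
  stats::cor(xv[ok], yv[ok])
}
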