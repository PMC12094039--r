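## Reporting windows aligned with ruminant feeding behavior: the overnight
## window wraps midnight. Half-open on the right, assigned by visit start.
WINDOW_LABELS <- c("22:00-04:00", "04:00-10:00", "10:00-16:00", "16:00-22:00")

#' Count records in four 6-hour time-of-day windows
#'
#' Each record is assigned by the hour of its start time to exactly one of
#' four half-open windows: 10 p.m.-4 a.m. (wrapping midnight), 4-10 a.m.,
#' 10 a.m.-4 p.m., 4-10 p.m. The counts always sum to the number of input
#' records.
#'
#' @param records Visit-record tibble.
#' @return Tibble with columns `window` (label) and `n`.
#' @export
#' @examples
#' # a record starting 03:59 falls in the overnight window; 04:00 in the next
time_window_counts <- function(records) {
  n <- integer(4)
  if (nrow(records) > 0) {
    h <- lubridate::hour(records$start_time) +
      lubridate::minute(records$start_time) / 60 +
      lubridate::second(records$start_time) / 3600
    idx <- ifelse(h >= 22 | h < 4, 1L,
                  ifelse(h < 10, 2L, ifelse(h < 16, 3L, 4L)))
    tab <- tabulate(idx, nbins = 4)
    n <- as.integer(tab)
  }
  tibble::tibble(window = WINDOW_LABELS, n = n)
}

#' Records per study date, with per-gas data counts
#'
#' One row per calendar date in the study window (zero-filled for days
#' without records): the number of visit records and, per gas, how many of
#' them carry data for that gas.
#'
#' @param records Visit-record tibble.
#' @param study A [study_window()]; inferred when omitted.
#' @return Tibble `date`, `n_records`, `n_CH4`, `n_CO2`, `n_O2`, `n_H2`.
#' @export
records_per_day <- function(records, study = NULL) {
  if (is.null(study)) {
    if (nrow(records) == 0) rlang::abort("records_per_day needs a study window for empty input")
    study <- infer_study(visits = records)
  }
  dates <- seq(study$start_date, study$end_date, by = "day")
  base <- tibble::tibble(date = dates)
  if (nrow(records) == 0) {
    base$n_records <- 0L
    for (g in GAS_NAMES) base[[paste0("n_", g)]] <- 0L
    return(base)
  }
  day <- as.Date(records$start_time, tz = "UTC")
  base$n_records <- as.integer(sapply(dates, function(d) sum(day == d)))
  for (g in GAS_NAMES) {
    has <- !is.na(records[[g]])
    base[[paste0("n_", g)]] <-
      as.integer(sapply(dates, function(d) sum(day == d & has)))
  }
  base
}

#' Per-animal visitation activity
#'
#' One row per animal seen in the records (plus roster animals with zero
#' records): total records, records per day over the whole study length,
#' and per-gas counts of records carrying data. An animal with 184 records
#' in a 46-day study has 184/46 = 4 records per day.
#'
#' @param records Visit-record tibble.
#' @param study A [study_window()]; its length in days is the denominator.
#' @param roster Optional roster; its `farm_id`s are zero-filled if unseen.
#' @return Tibble `animal_id`, `n_records`, `records_per_day`, and
#'   `n_CH4` ... `n_H2`.
#' @export
animal_activity <- function(records, study, roster = NULL) {
  stopifnot(inherits(study, "study_window"), study$n_days >= 1)
  ids <- sort(unique(c(
    records$animal_id,
    if (!is.null(roster)) as.character(roster$farm_id)
  )))
  out <- tibble::tibble(animal_id = ids)
  out$n_records <- as.integer(sapply(ids, function(a) sum(records$animal_id == a)))
  out$records_per_day <- out$n_records / study$n_days
  for (g in GAS_NAMES) {
    has <- !is.na(records[[g]])
    out[[paste0("n_", g)]] <-
      as.integer(sapply(ids, function(a) sum(records$animal_id == a & has)))
  }
  out
}

#' Mean gas production by time-of-day bin
#'
#' Unweighted per-bin means over all records without any filtering — the
#' raw diurnal emission profile. Bins partition the 24-hour day.
#'
#' @param records Visit-record tibble.
#' @param gases Gases to profile, default all four.
#' @param bin_minutes Bin width in minutes; must divide 1440. Default 60.
#' @return Tibble with `bin_start_min`, `bin_label`, `gas`, `n`, `mean`
#'   (one row per bin x gas; `n = 0` bins have missing means).
#' @export
diurnal_profile <- function(records, gases = GAS_NAMES, bin_minutes = 60) {
  stopifnot(all(gases %in% GAS_NAMES))
  if (1440 %% bin_minutes != 0) rlang::abort("bin_minutes must divide 1440")
  starts <- seq(0, 1439, by = bin_minutes)
  grid <- expand.grid(bin_start_min = starts, gas = gases,
                      stringsAsFactors = FALSE)
  grid$bin_label <- sprintf("%02d:%02d", grid$bin_start_min %/% 60,
                            grid$bin_start_min %% 60)
  grid <- tibble::as_tibble(grid[c("bin_start_min", "bin_label", "gas")])
  if (nrow(records) == 0) {
    grid$n <- 0L
    grid$mean <- NA_real_
    return(grid)
  }
  min_of_day <- lubridate::hour(records$start_time) * 60 +
    lubridate::minute(records$start_time)
  bin <- (min_of_day %/% bin_minutes) * bin_minutes
  grid$n <- 0L
  grid$mean <- NA_real_
  for (i in seq_len(nrow(grid))) {
    v <- records[[grid$gas[i]]][bin == grid$bin_start_min[i]]
    v <- v[!is.na(v)]
    grid$n[i] <- length(v)
    if (length(v) > 0) grid$mean[i] <- mean(v)
  }
  grid
}

five_number <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- min(v[v >= q[1] - 1.5 * iqr])
  hi <- max(v[v <= q[3] + 1.5 * iqr])
  c(whisker_low = lo, q1 = q[1], median = q[2], q3 = q[3], whisker_high = hi)
}

fmt_num <- function(x, digits = 1) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}

md_table <- function(df, digits = 1) {
  fmt_col <- function(col) {
    if (is.numeric(col) && !is.integer(col)) fmt_num(col, digits)
    else as.character(col)
  }
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  if (nrow(df) == 0) return(c(header, sep))
  cells <- vapply(df, fmt_col, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Render a Markdown monitoring report
#'
#' Assembles a plain-Markdown report of the visitation and gas data: animal
#' counts and the non-visitor list, records per day, per-animal activity
#' with the time-window distribution, and per-gas per-animal distribution
#' summaries (boxplot five-number summaries with 1.5*IQR whiskers). In
#' `"final"` mode the unfiltered diurnal profile table is appended. Only
#' the requested gases appear. Rendering is deterministic: every number in
#' the document is taken from the corresponding module output.
#'
#' @param records Visit-record tibble.
#' @param study A [study_window()]; inferred when omitted.
#' @param roster Optional roster for expected-animal and non-visitor lists.
#' @param plot_opt Gases to include: subset of `c("CH4","CO2","O2","H2")`
#'   or `"all"`.
#' @param mode `"daily"` (on-farm monitoring) or `"final"` (adds the
#'   diurnal profile of the finalized data).
#' @param path Optional file to write the report to.
#' @param fig_dir Optional directory: when given (and the records are
#'   non-empty), PNG figures of the per-animal gas distributions and the
#'   diurnal profile are written there and linked from the document.
#' @return Character vector of Markdown lines, invisibly if `path` is
#'   given.
#' @export
render_report <- function(records, study = NULL, roster = NULL,
                          plot_opt = "all", mode = c("daily", "final"),
                          path = NULL, fig_dir = NULL) {
  mode <- match.arg(mode)
  gases <- if (identical(plot_opt, "all")) GAS_NAMES else unique(plot_opt)
  bad <- setdiff(gases, GAS_NAMES)
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown gas name(s) in plot_opt: %s",
                         paste(bad, collapse = ", ")))
  }
  if (is.null(study)) {
    study <- if (nrow(records) > 0) infer_study(visits = records) else {
      study_window(Sys.Date(), Sys.Date())
    }
  }

  lines <- c(
    sprintf("# Gas monitoring report (%s)", mode),
    "",
    sprintf("Study window: %s to %s (%d days). Records: %d.",
            format(study$start_date), format(study$end_date),
            study$n_days, nrow(records)),
    ""
  )

  ## 1. animals and non-visitors
  seen <- sort(unique(records$animal_id))
  lines <- c(lines, "## Animals", "",
             sprintf("Animals with records: %d.", length(seen)))
  if (!is.null(roster)) {
    absent <- sort(setdiff(as.character(roster$farm_id), seen))
    lines <- c(lines,
               sprintf("Rostered animals: %d. Non-visitors: %s.",
                       nrow(roster),
                       if (length(absent)) paste(absent, collapse = ", ") else "none"))
  }
  lines <- c(lines, "")

  ## 2. records per day
  rpd <- records_per_day(records, study)
  rpd_show <- rpd[c("date", "n_records", paste0("n_", gases))]
  lines <- c(lines, "## Records per day", "", md_table(rpd_show), "")

  ## 3. per-animal activity + time windows
  act <- animal_activity(records, study, roster)
  act_show <- act[c("animal_id", "n_records", "records_per_day",
                    paste0("n_", gases))]
  lines <- c(lines, "## Records per animal", "", md_table(act_show, digits = 2), "")
  tw <- time_window_counts(records)
  lines <- c(lines, "## Records by time of day", "", md_table(tw), "")

  ## 4. per-gas per-animal distributions
  for (g in gases) {
    lines <- c(lines, sprintf("## %s distribution per animal (g/d)", g), "")
    rows <- lapply(seen, function(a) {
      v <- records[[g]][records$animal_id == a]
      v <- v[!is.na(v)]
      if (length(v) == 0) return(NULL)
      fn <- five_number(v)
      tibble::tibble(animal_id = a, n = length(v), mean = mean(v),
                     whisker_low = fn[["whisker_low"]], q1 = fn[["q1"]],
                     median = fn[["median"]], q3 = fn[["q3"]],
                     whisker_high = fn[["whisker_high"]])
    })
    rows <- dplyr::bind_rows(rows)
    if (nrow(rows) == 0) {
      lines <- c(lines, sprintf("No %s data.", g), "")
    } else {
      lines <- c(lines, md_table(rows), "")
    }
  }

  if (mode == "final") {
    prof <- diurnal_profile(records, gases)
    lines <- c(lines, "## Diurnal gas profile (all records, unfiltered)", "")
    wide <- tidyr::pivot_wider(prof[c("bin_label", "gas", "mean")],
                               names_from = "gas", values_from = "mean")
    lines <- c(lines, md_table(wide), "")
  }

  if (!is.null(fig_dir) && nrow(records) > 0) {
    figs <- write_report_figures(records, gases, fig_dir, mode)
    lines <- c(lines, "## Figures", "",
               sprintf("![%s](%s)", names(figs), figs), "")
  }

  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

write_report_figures <- function(records, gases, fig_dir, mode) {
  if (!dir.exists(fig_dir)) dir.create(fig_dir, recursive = TRUE)
  figs <- character(0)
  long <- tidyr::pivot_longer(records[c("animal_id", "start_time", gases)],
                              dplyr::all_of(gases), names_to = "gas",
                              values_to = "value")
  long <- long[!is.na(long$value), ]
  if (nrow(long) > 0) {
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$animal_id, y = .data$value)) +
      ggplot2::geom_boxplot(outlier.size = 0.5) +
      ggplot2::facet_wrap(~gas, scales = "free_y") +
      ggplot2::labs(x = "animal", y = "production (g/d)") +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
    f1 <- file.path(fig_dir, "gas_per_animal.png")
    ggplot2::ggsave(f1, p, width = 8, height = 5, dpi = 120)
    figs <- c(figs, "gas distribution per animal" = f1)
    if (mode == "final") {
      long$hour <- lubridate::hour(long$start_time) +
        lubridate::minute(long$start_time) / 60
      p2 <- ggplot2::ggplot(long, ggplot2::aes(x = .data$hour, y = .data$value)) +
        ggplot2::geom_point(alpha = 0.2, size = 0.4, colour = "grey50") +
        ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
        ggplot2::facet_wrap(~gas, scales = "free_y") +
        ggplot2::labs(x = "hour of day", y = "production (g/d)") +
        ggplot2::theme_bw()
      f2 <- file.path(fig_dir, "diurnal_profile.png")
      ggplot2::ggsave(f2, p2, width = 8, height = 5, dpi = 120)
      figs <- c(figs, "diurnal gas profile" = f2)
    }
  }
  figs
}
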