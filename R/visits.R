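#' Per-animal per-day visit counts
#'
#' Visitation monitoring from either input: feed-drop events (consecutive
#' drops grouped into visits with the same gap rule as [pellet_intakes()] —
#' early-trial monitoring must see visits too short to yield a valid
#' record) or preprocessed visit records (each record is one visit).
#' Includes a per-unit breakdown; counts are invariant to input row order.
#'
#' @param x A feed-drop event tibble (column `time`) or a visit-record
#'   tibble (column `start_time`).
#' @param study Optional [study_window()]; counts outside it are dropped.
#' @param gap_seconds Inter-event gap defining a new visit (events input
#'   only), default 300.
#' @return Tibble `animal_id`, `date`, `unit_id`, `n_visits`.
#' @export
visits_per_animal <- function(x, study = NULL, gap_seconds = 300) {
  if ("time" %in% names(x)) {
    ev <- assign_visit_groups(x, gap_seconds)
    if (nrow(ev) == 0) {
      vis <- tibble::tibble(animal_id = character(0),
                            date = as.Date(character(0)),
                            unit_id = character(0))
    } else {
      vis <- ev |>
        dplyr::group_by(.data$visit_group) |>
        dplyr::summarise(animal_id = .data$animal_id[1],
                         date = as.Date(.data$time[1], tz = "UTC"),
                         unit_id = .data$unit_id[1], .groups = "drop")
    }
  } else if ("start_time" %in% names(x)) {
    vis <- tibble::tibble(animal_id = x$animal_id,
                          date = as.Date(x$start_time, tz = "UTC"),
                          unit_id = x$unit_id)
  } else {
    rlang::abort("x must be a feed-event table (column 'time') or visit-record table (column 'start_time')")
  }
  if (!is.null(study)) {
    vis <- vis[vis$date >= study$start_date & vis$date <= study$end_date, ]
  }
  vis |>
    dplyr::count(.data$animal_id, .data$date, .data$unit_id, name = "n_visits") |>
    dplyr::arrange(.data$animal_id, .data$date, .data$unit_id)
}

#' Rostered animals with no visits in a trailing window
#'
#' Flags animals that are not using the unit(s) — most useful early in a
#' trial, when non-visitors need encouragement or training. The window is
#' the `window_days` days ending on the last day seen in the data (all
#' days when `window_days` is omitted). Visitors and non-visitors
#' partition the roster.
#'
#' @param x Feed-drop events or visit records (see [visits_per_animal()]).
#' @param roster Roster tibble (required): its `farm_id`s define the
#'   animals expected on trial.
#' @param window_days Optional trailing window length in days.
#' @param gap_seconds Passed to [visits_per_animal()].
#' @return Sorted character vector of non-visiting animal identifiers.
#' @export
nonvisitors <- function(x, roster, window_days = NULL, gap_seconds = 300) {
  if (is.null(roster) || nrow(roster) == 0) {
    rlang::abort("nonvisitors requires a non-empty roster")
  }
  vis <- visits_per_animal(x, gap_seconds = gap_seconds)
  if (!is.null(window_days) && nrow(vis) > 0) {
    last_day <- max(vis$date)
    vis <- vis[vis$date > last_day - window_days, ]
  }
  sort(setdiff(as.character(roster$farm_id), unique(vis$animal_id)))
}
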