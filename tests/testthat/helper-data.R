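# Builders and independent brute-force oracles used across the suite.

# Construct a visit-record tibble from parallel vectors (a row per visit).
make_visits <- function(animal = "A01", start = "2024-01-15 08:00:00",
                        dur = 3, CH4 = 375, CO2 = NA_real_, O2 = NA_real_,
                        H2 = NA_real_, unit = "GF1") {
  n <- max(length(animal), length(start), length(dur), length(CH4),
           length(CO2), length(O2), length(H2))
  start <- as.POSIXct(rep_len(start, n), tz = "UTC")
  dur <- rep_len(dur, n)
  tibble::tibble(
    animal_id = rep_len(animal, n),
    unit_id = rep_len(unit, n),
    start_time = start,
    end_time = start + dur * 60 + 30,
    good_duration_min = dur,
    CH4 = rep_len(as.numeric(CH4), n),
    CO2 = rep_len(as.numeric(CO2), n),
    O2 = rep_len(as.numeric(O2), n),
    H2 = rep_len(as.numeric(H2), n)
  )
}

make_events <- function(animal = "A01", time = "2024-01-15 08:00:00",
                        drops = 5L, unit = "GF1") {
  n <- max(length(animal), length(time), length(drops))
  tibble::tibble(
    animal_id = rep_len(animal, n),
    unit_id = rep_len(unit, n),
    time = as.POSIXct(rep_len(time, n), tz = "UTC"),
    drops = as.integer(rep_len(drops, n))
  )
}

# Brute-force daily averages: plain loops, no grouping verbs, independent of
# the implementation path.
bf_daily <- function(records, param1) {
  gases <- c("CH4", "CO2", "O2", "H2")
  records$date <- as.Date(records$start_time, tz = "UTC")
  keys <- unique(records[c("animal_id", "date")])
  keys <- keys[order(keys$animal_id, keys$date), ]
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- records[records$animal_id == keys$animal_id[i] &
                     records$date == keys$date[i], ]
    if (nrow(sub) < param1) next
    row <- list(animal_id = keys$animal_id[i], date = keys$date[i],
                n_records = nrow(sub),
                total_minutes = sum(sub$good_duration_min))
    for (g in gases) {
      x <- sub[[g]]; w <- sub$good_duration_min
      ok <- !is.na(x)
      row[[g]] <- if (any(ok)) sum(x[ok] * w[ok]) / sum(w[ok]) else NA_real_
    }
    rows[[length(rows) + 1]] <- tibble::as_tibble(row)
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

# Brute-force weekly averages from daily rows.
bf_weekly <- function(daily, param2, start_date) {
  gases <- c("CH4", "CO2", "O2", "H2")
  daily$week <- floor(as.numeric(daily$date - start_date) / 7) + 1
  keys <- unique(daily[c("animal_id", "week")])
  keys <- keys[order(keys$animal_id, keys$week), ]
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- daily[daily$animal_id == keys$animal_id[i] &
                   daily$week == keys$week[i], ]
    if (length(unique(sub$date)) < param2) next
    row <- list(animal_id = keys$animal_id[i],
                week_index = as.integer(keys$week[i]),
                n_days = length(unique(sub$date)),
                n_records = sum(sub$n_records),
                total_minutes = sum(sub$total_minutes))
    for (g in gases) {
      x <- sub[[g]]; w <- sub$total_minutes
      ok <- !is.na(x)
      row[[g]] <- if (any(ok)) sum(x[ok] * w[ok]) / sum(w[ok]) else NA_real_
    }
    rows[[length(rows) + 1]] <- tibble::as_tibble(row)
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

# A small, quick trial used by several files.
small_trial <- function(seed = 11, n_animals = 8L, n_days = 21L, ...) {
  simulate_trial(sim_config(n_animals = n_animals, n_days = n_days,
                            seed = seed, ...))
}
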