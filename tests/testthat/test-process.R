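test_that("process_params enforces the validity thresholds", {
  p <- process_params(2, 4, 2)
  expect_equal(p$param1, 2L)
  expect_error(process_params(0, 4, 2), "param1")
  expect_error(process_params(2, 0, 2), "param2")
  expect_error(process_params(2, 4, 1), "min_time")
  expect_error(process_params(2, 4, 2, outlier_k = 0), "outlier_k")
})

test_that("filter_min_time keeps the inclusive boundary and matches brute force", {
  expect_equal(nrow(filter_min_time(make_visits()[0, ], 2)), 0)
  v <- make_visits(dur = c(1.99, 2, 2.01, 5))
  kept <- filter_min_time(v, 2)
  expect_equal(kept$good_duration_min, c(2, 2.01, 5))
  expect_error(filter_min_time(v, 1), "min_time")

  sim <- small_trial(seed = 17, n_animals = 15L, n_days = 30L)$visits
  expect_gt(nrow(sim), 900)
  for (mt in c(2, 3)) {
    expect_equal(nrow(filter_min_time(sim, mt)),
                 sum(sim$good_duration_min >= mt))
  }
})

test_that("outlier masking is per gas, single pass, and drops empty records", {
  # identical values: SD = 0, the zero-width band contains its centre
  v <- make_visits(CH4 = rep(300, 10), CO2 = rep(12000, 10))
  out <- remove_gas_outliers(v, 3)
  expect_equal(nrow(out), 10)
  expect_equal(attr(out, "masked")[["CH4"]], 0L)

  # 99 values of 300 plus one 10,000: the outlier sits far beyond 3 SD
  vals <- c(rep(300, 99), 10000)
  m <- mean(vals); s <- sd(vals)
  expect_true(10000 > m + 3 * s && all(300 >= m - 3 * s))
  v <- make_visits(CH4 = vals, CO2 = rep(12000, 100))
  out <- remove_gas_outliers(v, 3)
  expect_equal(attr(out, "masked")[["CH4"]], 1L)
  expect_equal(sum(!is.na(out$CH4)), 99)
  # the record lost CH4 but keeps CO2, so it is not dropped
  expect_equal(nrow(out), 100)

  # a record missing every gas after masking is dropped
  v1 <- make_visits(CH4 = vals)
  out1 <- remove_gas_outliers(v1, 3)
  expect_equal(nrow(out1), 99)

  # single pass: statistics are not recomputed after masking
  vals2 <- c(rep(300, 60), 900, 20000)
  m2 <- mean(vals2); s2 <- sd(vals2)
  stopifnot(900 < m2 + 3 * s2,               # survives the single pass
            900 > mean(c(rep(300, 60), 900)) + 3 * sd(c(rep(300, 60), 900)))
  out2 <- remove_gas_outliers(make_visits(CH4 = vals2, CO2 = 12000), 3)
  expect_true(900 %in% out2$CH4)
  expect_false(20000 %in% out2$CH4)

  # <= 1 non-missing value: SD undefined, nothing masked
  v3 <- make_visits(CH4 = c(5000, rep(NA, 5)), CO2 = 12000)
  expect_equal(attr(remove_gas_outliers(v3, 3), "masked")[["CH4"]], 0L)
})

test_that("daily averages are duration-weighted with the param1 threshold", {
  v <- make_visits(start = c("2024-01-15 08:00:00", "2024-01-15 14:00:00"),
                   dur = c(2, 4), CH4 = c(300, 360))
  d <- daily_averages(v, param1 = 2)
  expect_equal(d$CH4, (2 * 300 + 4 * 360) / 6) # = 340
  expect_equal(d$n_records, 2L)
  expect_equal(d$total_minutes, 6)

  expect_equal(nrow(daily_averages(make_visits(), param1 = 2)), 0)

  # gas with no valid values that day is missing, never 0
  v$CO2 <- NA_real_
  expect_true(is.na(daily_averages(v, 2)$CO2))
})

test_that("equal durations reduce the weighted mean to the arithmetic mean", {
  set.seed(31)
  for (i in 1:500) {
    k <- sample(2:6, 1)
    ch4 <- runif(k, 200, 600)
    v <- make_visits(start = sprintf("2024-01-15 %02d:00:00", seq_len(k) + 5),
                     dur = 3, CH4 = ch4)
    expect_equal(daily_averages(v, 1)$CH4, mean(ch4))
  }
})

test_that("weekly averages are minute-weighted, anchored at the study start", {
  study <- study_window("2024-01-15", "2024-02-29")
  daily <- tibble::tibble(
    animal_id = "A01",
    date = as.Date("2024-01-15") + 0:3,
    n_records = 2L, total_minutes = 10,
    CH4 = c(360, 370, 380, 390), CO2 = NA_real_, O2 = NA_real_, H2 = NA_real_
  )
  w <- weekly_averages(daily, param2 = 4, study)
  expect_equal(w$CH4, 375)
  expect_equal(w$week_index, 1L)
  expect_equal(w$n_days, 4L)

  # 3 days with records < param2 = 4: no row
  expect_equal(nrow(weekly_averages(daily[1:3, ], 4, study)), 0)

  # day 8 of the study belongs to week 2, not ISO weeks
  daily2 <- daily
  daily2$date <- as.Date("2024-01-22") + 0:3
  expect_equal(weekly_averages(daily2, 4, study)$week_index, 2L)
})

test_that("daily and weekly means match brute-force recomputation on simulations", {
  study <- study_window("2024-01-15", "2024-02-29")
  trial <- simulate_trial(sim_config(n_animals = 12L, n_days = 46L, seed = 23))
  res <- process_records(trial$visits, process_params(1, 1, 2), study)
  d_bf <- bf_daily(remove_gas_outliers(filter_min_time(trial$visits, 2), 3), 1)
  expect_equal(as.data.frame(res$daily), as.data.frame(d_bf),
               tolerance = 1e-12)
  w_bf <- bf_weekly(d_bf, 1, study$start_date)
  expect_gt(nrow(w_bf), 50)
  expect_equal(as.data.frame(res$weekly)[names(w_bf)], as.data.frame(w_bf),
               tolerance = 1e-12)
})

test_that("process_records composes the four stages and logs the audit trail", {
  expect_equal(nrow(process_records(make_visits()[0, ],
                                    process_params(2, 4, 2),
                                    study_window("2024-01-15", "2024-01-21"))$daily), 0)

  # noiseless herd: every daily and weekly mean equals the herd mean
  cfg <- sim_config(n_animals = 4L, n_days = 7L, visit_rate_per_day = 3,
                    animal_sd = c(CH4 = 0, CO2 = 0, O2 = 0, H2 = 0),
                    visit_sd = c(CH4 = 0, CO2 = 0, O2 = 0, H2 = 0),
                    diurnal_amplitude = 0, outlier_prob = 0, seed = 2)
  tr <- simulate_trial(cfg)
  res <- process_records(tr$visits, process_params(2, 4, 2),
                         study_window(cfg$start_date, cfg$start_date + 6))
  expect_equal(res$daily$CH4, rep(375, nrow(res$daily)))
  expect_equal(res$weekly$CH4, rep(375, nrow(res$weekly)))

  # composition equals running the stages by hand
  tr2 <- small_trial(seed = 29, n_animals = 16L, n_days = 54L)
  expect_gt(nrow(tr2$visits), 1800)
  study <- study_window(min(as.Date(tr2$visits$start_time)),
                        max(as.Date(tr2$visits$start_time)))
  params <- process_params(2, 4, 2)
  res2 <- process_records(tr2$visits, params, study)
  manual_f <- remove_gas_outliers(filter_min_time(tr2$visits, 2), 3)
  manual_d <- daily_averages(manual_f, 2)
  manual_w <- weekly_averages(manual_d, 4, study)
  expect_equal(res2$daily, manual_d, ignore_attr = TRUE)
  expect_equal(res2$weekly, manual_w, ignore_attr = TRUE)
  cn <- res2$counts
  expect_equal(cn$rows_in, nrow(tr2$visits))
  expect_equal(cn$after_min_time, nrow(filter_min_time(tr2$visits, 2)))
  expect_equal(cn$daily_rows, nrow(manual_d))
})

test_that("summarize_gas reports n, mean, sample SD, CV and range", {
  s1 <- summarize_gas(5)
  expect_equal(s1$n, 1)
  expect_equal(s1$sd, 0)
  expect_equal(s1$cv, 0)
  s2 <- summarize_gas(c(10, 20))
  expect_equal(s2$mean, 15)
  expect_equal(s2$sd, sqrt(50), tolerance = 1e-12)
  expect_equal(s2$cv, 100 * sqrt(50) / 15, tolerance = 1e-12)
  expect_equal(c(s2$min, s2$max), c(10, 20))
  expect_error(summarize_gas(NA_real_), "at least one")

  v <- simulate_trial(paper_like_config(seed = 13, n_animals = 32L,
                                        n_days = 135L))$visits
  expect_gt(nrow(v), 9000)
  expect_lt(abs(summarize_gas(v$CH4)$mean - 375) / 375, 0.05)
})

test_that("weighted means are convex combinations of their inputs", {
  trial <- small_trial(seed = 37)
  res <- process_records(trial$visits, process_params(1, 1, 2))
  filt <- remove_gas_outliers(filter_min_time(trial$visits, 2), 3)
  filt$date <- as.Date(filt$start_time)
  for (i in sample(nrow(res$daily), 50)) {
    sub <- filt[filt$animal_id == res$daily$animal_id[i] &
                  filt$date == res$daily$date[i], ]
    ch4 <- sub$CH4[!is.na(sub$CH4)]
    if (length(ch4) == 0) next
    expect_gte(res$daily$CH4[i], min(ch4) - 1e-9)
    expect_lte(res$daily$CH4[i], max(ch4) + 1e-9)
  }
})

test_that("param_grid matches process_records and is monotone in its parameters", {
  trial <- small_trial(seed = 41, n_animals = 16L, n_days = 28L)
  study <- study_window(min(as.Date(trial$visits$start_time)),
                        max(as.Date(trial$visits$start_time)))
  g1 <- param_grid(trial$visits, 2, 4, 2, study)
  res <- process_records(trial$visits, process_params(2, 4, 2), study)
  expect_equal(g1$n_daily_records, nrow(res$daily))
  expect_equal(g1$n_animals_daily, length(unique(res$daily$animal_id)))
  expect_equal(g1$n_weekly_records, nrow(res$weekly))
  expect_equal(g1$daily_mean, mean(res$daily$CH4, na.rm = TRUE))

  grid <- param_grid(trial$visits, 1:3, 3:7, 2:3, study)
  expect_equal(nrow(grid), 3 * 5 * 2)
  expect_true(all(grid$n_weekly_records <= grid$n_daily_records))
  expect_true(all(grid$n_animals_weekly <= grid$n_animals_daily))
  cols <- c("n_daily_records", "n_animals_daily", "n_weekly_records",
            "n_animals_weekly")
  for (cc in cols) {
    # non-increasing in param1 and min_time for every fixed other pair
    for (p2 in 3:7) for (mt in 2:3) {
      sub <- grid[grid$param2 == p2 & grid$min_time == mt, ]
      expect_true(all(diff(sub[[cc]][order(sub$param1)]) <= 0))
    }
    for (p1 in 1:3) for (p2 in 3:7) {
      sub <- grid[grid$param1 == p1 & grid$param2 == p2, ]
      expect_true(all(diff(sub[[cc]][order(sub$min_time)]) <= 0))
    }
  }
})

test_that("grid_correlation matches the textbook formula and handles edge cases", {
  grid <- tibble::tibble(param1 = rep(1:3, each = 3),
                         n_daily_records = c(9, 8, 7, 7, 6, 5, 4, 4, 2),
                         flat = 1)
  r <- grid_correlation(grid, "param1", "n_daily_records")
  x <- grid$param1; y <- grid$n_daily_records
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r, r_hand, tolerance = 1e-12)
  expect_lt(r, 0)
  grid$y <- grid$param1
  expect_equal(grid_correlation(grid, "param1", "y"), 1)
  expect_true(is.na(grid_correlation(grid, "param1", "flat")))
  expect_true(is.na(grid_correlation(grid[1:2, ], "param1", "n_daily_records")))
})
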