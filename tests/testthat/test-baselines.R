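make_profiles <- function(values_by_date, bins = 0:23) {
  purrr::imap_dfr(values_by_date, function(v, d) {
    tibble::tibble(date = as.Date(d), bin = bins, value = v)
  })
}

test_that("usual pattern of identical days is the day with zero sd", {
  profile <- c(rep(0, 6), 1, 3, 5, 2, rep(4, 12), 2, 1)
  dates <- as.Date("2023-03-01") + 0:20
  dp <- make_profiles(stats::setNames(rep(list(profile), 21),
                                      as.character(dates)))
  up <- usual_pattern(dp, as_of = as.Date("2023-03-22"))
  expect_true(up$available)
  expect_equal(length(up$contributing_dates), 21)
  expect_equal(tidy(up)$mean, profile)
  expect_equal(tidy(up)$sd, rep(0, 24))
})

test_that("usual pattern averages alternating profiles", {
  dates <- as.Date("2023-03-01") + 0:19
  vals <- lapply(seq_along(dates), function(i) {
    v <- rep(0, 24); v[4] <- if (i %% 2 == 0) 0 else 2; v
  })
  dp <- make_profiles(stats::setNames(vals, as.character(dates)))
  up <- usual_pattern(dp, as_of = as.Date("2023-03-21"), window_days = 20)
  expect_equal(tidy(up)$mean[tidy(up)$bin == 3], 1.0)
})

test_that("insufficient history flags the pattern unavailable", {
  dates <- as.Date("2023-03-01") + 0:4
  dp <- make_profiles(stats::setNames(rep(list(rep(1, 24)), 5),
                                      as.character(dates)))
  up <- usual_pattern(dp, as_of = as.Date("2023-03-06"))
  expect_false(up$available)
  expect_error(deviation_bounds(up), "unavailable")
  expect_error(difference_series(tibble::tibble(bin = 0:23, value = 0), up),
               "unavailable")
})

test_that("the displayed day is excluded from its own pattern", {
  dates <- as.Date("2023-03-01") + 0:20
  vals <- c(rep(list(rep(2, 24)), 20), list(rep(100, 24)))
  dp <- make_profiles(stats::setNames(vals, as.character(dates)))
  up <- usual_pattern(dp, as_of = dates[21])
  expect_equal(tidy(up)$mean, rep(2, 24))
})

test_that("running average matches hand-computed trailing means", {
  s <- tibble::tibble(date = as.Date("2023-03-01") + 0:3, value = 1:4)
  ra <- running_average(s, window_days = 2)
  expect_equal(ra$smoothed, c(1, 1.5, 2.5, 3.5))
  # constant series is a fixed point for any window
  s2 <- tibble::tibble(date = as.Date("2023-03-01") + 0:9, value = 5)
  expect_equal(running_average(s2, window_days = 4)$smoothed, rep(5, 10))
  # missing day: mean over the present values in the window
  s3 <- tibble::tibble(date = as.Date("2023-03-01") + 0:2,
                       value = c(3, NA, 6))
  expect_equal(running_average(s3, window_days = 3)$smoothed[3], 4.5)
  # all-missing window stays missing
  s4 <- tibble::tibble(date = as.Date("2023-03-01") + 0:1,
                       value = c(NA, NA))
  expect_true(all(is.na(running_average(s4, window_days = 2)$smoothed)))
  expect_equal(glance(running_average(s4, 2))$n_missing, 2)
})

test_that("difference series is signed actual minus usual", {
  dates <- as.Date("2023-03-01") + 0:20
  base <- rep(4, 24)
  dp <- make_profiles(stats::setNames(rep(list(base), 21),
                                      as.character(dates)))
  up <- usual_pattern(dp, as_of = as.Date("2023-03-22"))
  actual <- tibble::tibble(bin = 0:23, value = base)
  d0 <- difference_series(actual, up)
  expect_equal(d0$difference, rep(0, 24))
  actual$value[4] <- 7
  d1 <- difference_series(actual, up)
  expect_equal(d1$difference[d1$bin == 3], 3)
  expect_error(
    difference_series(tibble::tibble(bin = 0:11, value = 0), up),
    "bin structures")
})

test_that("deviation bounds are mean +/- k sd and scale linearly in k", {
  dates <- as.Date("2023-03-01") + 0:9
  vals <- lapply(1:10, function(i) c(if (i <= 5) 8 else 12, rep(0, 23)))
  dp <- make_profiles(stats::setNames(vals, as.character(dates)))
  up <- usual_pattern(dp, as_of = as.Date("2023-03-11"), window_days = 10)
  b1 <- deviation_bounds(up, k = 1)
  expect_equal(b1$mean[1], 10)
  expect_equal(b1$upper[1] - b1$mean[1], sd(c(rep(8, 5), rep(12, 5))))
  b2 <- deviation_bounds(up, k = 2)
  expect_equal(b2$upper[1] - b2$lower[1], 2 * (b1$upper[1] - b1$lower[1]))
  # zero-sd bins collapse onto the mean
  expect_equal(b1$lower[2], b1$mean[2])
})

test_that("usual pattern commutes with day-part aggregation on identical days", {
  sched <- generate_schedule(behavior_profile(), n_days = 2, seed = 51)
  ev <- simulate_motion_events(sched)
  d <- sched$nights$anchor_date[1]
  # same day's profile replicated: hourly and day-part patterns must agree
  hp <- daily_hourly_profiles(ev, rep(d, 1))
  dpp <- daily_day_part_profiles(ev, rep(d, 1))
  dates <- as.Date("2023-04-01") + 0:9
  hourly <- purrr::map_dfr(dates, function(dd)
    dplyr::mutate(hp, date = dd))
  dayparts <- purrr::map_dfr(dates, function(dd)
    dplyr::mutate(dpp, date = dd))
  up_h <- usual_pattern(hourly, as_of = max(dates) + 1, window_days = 11)
  up_d <- usual_pattern(dayparts, as_of = max(dates) + 1, window_days = 11)
  th <- tidy(up_h)
  agg_daytime <- sum(th$mean[th$bin %in% 10:21])
  expect_equal(tidy(up_d)$mean[tidy(up_d)$bin == "daytime"], agg_daytime)
  agg_morning <- sum(th$mean[th$bin %in% 6:9])
  expect_equal(tidy(up_d)$mean[tidy(up_d)$bin == "morning"], agg_morning)
})

test_that("glance and tidy report the pattern metadata", {
  dates <- as.Date("2023-03-01") + 0:20
  dp <- make_profiles(stats::setNames(rep(list(rep(1, 24)), 21),
                                      as.character(dates)))
  up <- usual_pattern(dp, as_of = as.Date("2023-03-22"))
  g <- glance(up)
  expect_equal(g$n_days, 21)
  expect_equal(g$n_bins, 24)
  expect_true(g$available)
})
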