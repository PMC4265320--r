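test_that("single uninterrupted night yields the identity features", {
  w <- night_window("2023-03-01", "Europe/London")
  iv <- mk_intervals("2023-03-01 22:00:00", "2023-03-02 07:00:00")
  u <- extract_usage_features(iv, w)
  expect_equal(u$time_in_bed, pt("2023-03-01 22:00:00"))
  expect_equal(u$time_out_of_bed, pt("2023-03-02 07:00:00"))
  expect_equal(u$total_period_in_bed, 9L * 3600L)
  expect_equal(u$accumulated_period_in_bed, 9L * 3600L)
  expect_equal(u$accumulated_period_out_of_bed, 0L)
  expect_equal(u$continuity, 1.0)
  expect_equal(u$mean_time, pt("2023-03-02 02:30:00"))
  expect_false(u$window_truncated)
  expect_true(is.na(u$usage_reason))
})

test_that("interrupted night: centroid mean time and continuity 8/9", {
  w <- night_window("2023-03-01")
  iv <- mk_intervals(c("2023-03-01 22:00:00", "2023-03-02 03:00:00"),
                     c("2023-03-02 02:00:00", "2023-03-02 07:00:00"))
  u <- extract_usage_features(iv, w)
  expect_equal(u$total_period_in_bed, 9L * 3600L)
  expect_equal(u$accumulated_period_in_bed, 8L * 3600L)
  expect_equal(u$accumulated_period_out_of_bed, 1L * 3600L)
  expect_equal(u$continuity, 8 / 9, tolerance = 1e-12)
  # centroid oracle: (4h x 00:00 + 4h x 05:00) / 8h = 02:30
  expect_equal(u$mean_time, pt("2023-03-02 02:30:00"))
})

test_that("empty windows produce missing features with a reason code", {
  w <- night_window("2023-03-01")
  u <- extract_usage_features(mk_intervals(character(0), character(0)), w)
  expect_true(is.na(u$time_in_bed))
  expect_equal(u$total_period_in_bed, 0L)
  expect_equal(u$usage_reason, "no_usage_events")
})

test_that("an interval in progress at 18:00 counts, clipped and flagged", {
  w <- night_window("2023-03-01")
  iv <- mk_intervals("2023-03-01 16:00:00", "2023-03-02 07:00:00")
  u <- extract_usage_features(iv, w)
  expect_equal(u$time_in_bed, pt("2023-03-01 18:00:00"))
  expect_true(u$window_truncated)
})

test_that("usage feature identities hold on random interval sets", {
  set.seed(41)
  w <- night_window("2023-03-01")
  for (i in 1:100) {
    n <- sample(1:6, 1)
    # random sorted non-overlapping intervals inside the window, whole seconds
    bounds <- sort(sample.int(18 * 3600 - 1, 2 * n))
    iv <- mk_intervals(w$start + bounds[seq(1, 2 * n, 2)],
                       w$start + bounds[seq(2, 2 * n, 2)])
    u <- extract_usage_features(iv, w)
    expect_identical(u$accumulated_period_in_bed +
                       u$accumulated_period_out_of_bed,
                     u$total_period_in_bed)
    expect_gt(u$continuity, 0)
    expect_lte(u$continuity, 1)
    expect_true(u$mean_time >= u$time_in_bed & u$mean_time <= u$time_out_of_bed)
  }
})

test_that("adding an exit never increases continuity", {
  w <- night_window("2023-03-01")
  base <- mk_intervals("2023-03-01 22:00:00", "2023-03-02 07:00:00")
  u0 <- extract_usage_features(base, w)
  split <- mk_intervals(c("2023-03-01 22:00:00", "2023-03-02 03:10:00"),
                        c("2023-03-02 03:00:00", "2023-03-02 07:00:00"))
  u1 <- extract_usage_features(split, w)
  expect_lt(u1$continuity, u0$continuity)
  expect_equal(u1$time_in_bed, u0$time_in_bed)
  expect_equal(u1$time_out_of_bed, u0$time_out_of_bed)
})

test_that("nocturnal inactivity is the longest qualifying gap", {
  w <- night_window("2023-03-01")
  # two events only: the whole span between them is the gap
  m <- extract_motion_inactivity(
    mk_motion_stream(c("2023-03-01 21:50:00", "2023-03-02 06:40:00")), w)
  expect_equal(m$start_of_inactivity, pt("2023-03-01 21:50:00"))
  expect_equal(m$end_of_inactivity, pt("2023-03-02 06:40:00"))
  expect_equal(m$duration_of_inactivity, 8L * 3600L + 50L * 60L)
  expect_equal(m$mean_time_of_inactivity, pt("2023-03-02 02:15:00"))
  expect_false(m$inactivity_censored_start)

  # brute force over all gaps picks 23:00-06:30
  ev <- mk_motion_stream(c("2023-03-01 21:00:00", "2023-03-01 23:00:00",
                           "2023-03-02 06:30:00"))
  m2 <- extract_motion_inactivity(ev, w)
  expect_equal(m2$start_of_inactivity, pt("2023-03-01 23:00:00"))
  expect_equal(m2$duration_of_inactivity, 7L * 3600L + 30L * 60L)
})

test_that("inactivity handles degenerate nights via reason codes", {
  w <- night_window("2023-03-01")
  # events every 30 min all night: no gap reaches 3 h
  times <- seq(pt("2023-03-01 18:00:00"), pt("2023-03-02 12:00:00"),
               by = 1800)
  m <- extract_motion_inactivity(mk_motion_stream(times), w)
  expect_equal(m$motion_reason, "no_qualifying_gap")
  expect_equal(m$duration_of_inactivity, 0L)
  # no events at all
  m2 <- extract_motion_inactivity(mk_motion_stream(pt(character(0))), w)
  expect_equal(m2$motion_reason, "no_motion_events")
  # single evening event: morning edge censored at the window boundary
  m3 <- extract_motion_inactivity(
    mk_motion_stream("2023-03-01 21:00:00"), w)
  expect_equal(m3$start_of_inactivity, pt("2023-03-01 21:00:00"))
  expect_equal(m3$end_of_inactivity, w$end)
  expect_true(m3$inactivity_censored_end)
})

test_that("inactivity interior contains no motion events", {
  set.seed(43)
  for (i in 1:20) {
    w <- night_window("2023-03-01")
    times <- w$start + sort(sample.int(18 * 3600 - 1, sample(2:12, 1)))
    m <- extract_motion_inactivity(mk_motion_stream(times), w)
    if (is.na(m$motion_reason)) {
      inside <- times > m$start_of_inactivity & times < m$end_of_inactivity
      expect_equal(sum(inside), 0)
      expect_equal(
        as.numeric(m$end_of_inactivity - m$start_of_inactivity,
                   units = "secs"),
        m$duration_of_inactivity)
    }
  }
})

test_that("nightly table is complete with reason-coded gaps", {
  sched <- generate_schedule(behavior_profile(), n_days = 7, seed = 13)
  ev <- simulate_events(sched)
  dates <- sched$nights$anchor_date
  ft <- nightly_feature_table(ev, dates)
  expect_equal(nrow(ft), 7)
  expect_identical(ft$anchor_date, dates)
  ok <- is.na(ft$usage_reason)
  expect_identical(ft$accumulated_period_in_bed[ok] +
                     ft$accumulated_period_out_of_bed[ok],
                   ft$total_period_in_bed[ok])
  # a night with a sensor outage stays present, flagged
  w4 <- night_window(dates[4])
  ev_gap <- dplyr::filter(ev, !(sensor_type == "usage" &
                                  timestamp >= w4$start &
                                  timestamp <= w4$end))
  ft2 <- nightly_feature_table(validate_event_stream(ev_gap), dates)
  expect_equal(nrow(ft2), 7)
  expect_equal(ft2$usage_reason[4], "no_usage_events")
  expect_error(nightly_feature_table(ev, as.Date(character())), "empty")
})

test_that("features recover simulated bed and wake times exactly", {
  sched <- generate_schedule(behavior_profile(), n_days = 10, seed = 29)
  ev <- simulate_events(sched)
  ft <- nightly_feature_table(ev, sched$nights$anchor_date)
  err_in <- abs(as.numeric(ft$time_in_bed - sched$nights$bed_start,
                           units = "mins"))
  err_out <- abs(as.numeric(ft$time_out_of_bed - sched$nights$bed_end,
                            units = "mins"))
  expect_lte(median(err_in), 1)
  expect_lte(median(err_out), 1)
})
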