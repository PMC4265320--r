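test_that("dead-time model matches a brute-force walk over trigger lists", {
  base <- pt("2023-03-01 12:00:00")
  # triggers every 10 s over [0, 600): emissions at 0,120,240,360,480
  trig <- base + seq(0, 590, by = 10)
  out <- apply_dead_time(trig, 120)
  expect_equal(as.numeric(out - base, units = "secs"),
               c(0, 120, 240, 360, 480))
  # single trigger passes through
  expect_equal(apply_dead_time(base, 120), base)
  # gap exceeding the dead time: both emitted
  expect_length(apply_dead_time(base + c(0, 121), 120), 2)
  # gap exactly the dead time: both emitted (>=, not >)
  expect_length(apply_dead_time(base + c(0, 120), 120), 2)
  # gap just under: second suppressed
  expect_length(apply_dead_time(base + c(0, 119), 120), 1)
})

test_that("usage registration suppresses sub-threshold states inclusively", {
  # isolated occupancy durations 10, 29, 30, 300 s: only 30 and 300 register
  base <- pt("2023-03-01 12:00:00")
  for (d in c(10, 29)) {
    reg <- apply_usage_registration(
      mk_intervals(base, base + d), 30)
    expect_equal(nrow(reg), 0)
  }
  for (d in c(30, 300)) {
    reg <- apply_usage_registration(
      mk_intervals(base, base + d), 30)
    expect_equal(nrow(reg), 1)
    expect_equal(as.numeric(reg$end - reg$start, units = "secs"), d)
  }
  # sub-threshold vacancy merged into surrounding occupancy
  iv <- mk_intervals(c("2023-03-01 22:00:00", "2023-03-02 03:00:20"),
                     c("2023-03-02 03:00:00", "2023-03-02 07:00:00"))
  reg <- apply_usage_registration(iv, 30)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, pt("2023-03-01 22:00:00"))
  expect_equal(reg$end, pt("2023-03-02 07:00:00"))
  # vacancy at exactly the threshold is kept (two intervals)
  iv2 <- mk_intervals(c("2023-03-01 22:00:00", "2023-03-02 03:00:30"),
                      c("2023-03-02 03:00:00", "2023-03-02 07:00:00"))
  expect_equal(nrow(apply_usage_registration(iv2, 30)), 2)
})

test_that("simulated usage events reflect exits above the threshold only", {
  prof <- behavior_profile(nocturnal_exits_rate = 0)
  sched <- generate_schedule(prof, n_days = 1, seed = 3)
  # hand-place one 45 s exit at 03:00
  d <- sched$nights$anchor_date[1]
  sched$exits <- tibble::tibble(
    anchor_date = d,
    start = pt(paste(d + 1, "03:00:00")),
    end = pt(paste(d + 1, "03:00:45")))
  ev <- simulate_usage_events(sched)
  expect_equal(ev$event_kind,
               c("usage_start", "usage_end", "usage_start", "usage_end"))
  expect_equal(ev$timestamp[2], pt(paste(d + 1, "03:00:00")))
  expect_equal(ev$timestamp[3], pt(paste(d + 1, "03:00:45")))
  # a 20 s exit is suppressed: single start/end pair
  sched$exits$end <- pt(paste(d + 1, "03:00:20"))
  ev2 <- simulate_usage_events(sched)
  expect_equal(ev2$event_kind, c("usage_start", "usage_end"))
})

test_that("schedules are deterministic given a seed and respect Poisson(0)", {
  prof <- behavior_profile(nocturnal_exits_rate = 0)
  s1 <- generate_schedule(prof, n_days = 5, seed = 99)
  s2 <- generate_schedule(prof, n_days = 5, seed = 99)
  expect_identical(s1$nights, s2$nights)
  expect_identical(s1$motion, s2$motion)
  expect_equal(nrow(s1$exits), 0)
  s3 <- generate_schedule(prof, n_days = 5, seed = 100)
  expect_false(identical(s1$nights, s3$nights))
})

test_that("latent motion counts match the Poisson rate within 3 SE", {
  prof <- behavior_profile(daytime_motion_rate = 10,
                           nocturnal_exits_rate = 0)
  sched <- generate_schedule(prof, n_days = 100, seed = 21)
  oob <- schedule_out_of_bed(sched)
  hours <- sum(as.numeric(oob$end - oob$start, units = "hours"))
  expected <- 10 * hours
  observed <- nrow(sched$motion)
  expect_lt(abs(observed - expected), 3 * sqrt(expected))
})

test_that("emitted event streams respect the sensor physics invariants", {
  set.seed(5)
  for (seed in c(1, 2, 3)) {
    sched <- generate_schedule(behavior_profile(), n_days = 7, seed = seed)
    mot <- simulate_motion_events(sched)
    gaps <- diff(as.numeric(mot$timestamp))
    expect_true(all(gaps >= 120))
    usage <- simulate_usage_events(sched)
    iv <- suppressWarnings(pair_occupancy(usage))
    durs <- as.numeric(iv$end - iv$start, units = "secs")
    expect_true(all(durs >= 30))
    if (nrow(iv) > 1) {
      gaps_u <- as.numeric(iv$start[-1] - iv$end[-nrow(iv)], units = "secs")
      expect_true(all(gaps_u >= 30))
    }
  }
})

test_that("delayed_bedtime shifts only the targeted night", {
  sched <- generate_schedule(behavior_profile(), n_days = 12, seed = 8)
  d10 <- sched$nights$anchor_date[10]
  mod <- inject_anomaly(sched, "delayed_bedtime", d10, magnitude = 90,
                        seed = 2)
  expect_equal(as.numeric(mod$nights$bed_start[10] -
                            sched$nights$bed_start[10], units = "mins"), 90)
  expect_identical(mod$nights$bed_start[-10], sched$nights$bed_start[-10])
  expect_identical(mod$nights$bed_end, sched$nights$bed_end)
  # untargeted days' motion unchanged
  day10 <- sched$nights$bed_start[10]
  before <- sched$motion$timestamp[sched$motion$timestamp < day10]
  after_mod <- mod$motion$timestamp[mod$motion$timestamp < day10]
  expect_identical(before, after_mod)
})

test_that("increased_exits triples the mean exit count on targeted days", {
  # Monte-Carlo over seeds: expected exits on targeted nights ~ rate x 3
  prof <- behavior_profile(nocturnal_exits_rate = 1, exit_duration_mean = 4,
                           daytime_motion_rate = 2)
  n_rep <- 200
  counts <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    sched <- generate_schedule(prof, n_days = 3, seed = 1000 + r)
    tgt <- sched$nights$anchor_date[2]
    mod <- inject_anomaly(sched, "increased_exits", tgt, magnitude = 3,
                          seed = 2000 + r)
    counts[r] <- sum(mod$exits$anchor_date == tgt)
  }
  # mean of Poisson(3) over 200 reps: SE = sqrt(3/200) ~ 0.12
  expect_lt(abs(mean(counts) - 3), 4 * sqrt(3 / n_rep))
})

test_that("reduced_daytime_activity halves the trigger rate on targeted days", {
  prof <- behavior_profile(daytime_motion_rate = 12,
                           nocturnal_exits_rate = 0)
  n_rep <- 50
  ratio <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    sched <- generate_schedule(prof, n_days = 4, seed = 3000 + r)
    tgt <- sched$nights$anchor_date[2]
    mod <- inject_anomaly(sched, "reduced_daytime_activity", tgt,
                          magnitude = 0.5, seed = 4000 + r)
    day <- as.Date(format(sched$motion$timestamp, "%Y-%m-%d"))
    n_before <- sum(day == tgt)
    day_m <- as.Date(format(mod$motion$timestamp, "%Y-%m-%d"))
    ratio[r] <- sum(day_m == tgt) / n_before
  }
  expect_lt(abs(mean(ratio) - 0.5), 0.05)
})

test_that("anomaly injection validates its inputs", {
  sched <- generate_schedule(behavior_profile(), n_days = 3, seed = 1)
  expect_error(inject_anomaly(sched, "delayed_bedtime", as.Date(character()),
                              90), "empty")
  expect_error(inject_anomaly(sched, "delayed_bedtime",
                              as.Date("2030-01-01"), 90), "within")
  expect_error(inject_anomaly(sched, "longer_naps",
                              sched$nights$anchor_date[1], 1))
})

test_that("behavior profiles validate their clock-time constraints", {
  expect_error(behavior_profile(bed_time_mean = "15:00"), "bed_time_mean")
  expect_error(behavior_profile(wake_time_mean = "14:00"), "wake_time_mean")
  expect_silent(behavior_profile(bed_time_mean = "01:30"))
})
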