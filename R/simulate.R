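#' Behavior profile for the synthetic patient simulator
#'
#' Describes the daily behavior of a simulated single-occupant home: when the
#' subject typically goes to bed and wakes (normal around the stated clock
#' means), how often they leave the bed during the night (Poisson count per
#' night, exponential exit durations), and how often the living-room motion
#' sensor is triggered while they are up and about (Poisson process). Motion
#' in bed is invisible by design: the motion sensor is placed so the bed is
#' outside its field of view.
#'
#' Defaults describe a frail-elderly routine: bed around 22:30, up around
#' 07:00, one to two short bathroom visits per night, and a trigger every
#' ~7-8 minutes while active during the day.
#'
#' @param bed_time_mean,wake_time_mean clock times `"HH:MM"`. Bed time must
#'   fall in \[18:00, 02:00) (times before 02:00 are read as after midnight);
#'   wake time in (04:00, 12:00\].
#' @param bed_time_sd,wake_time_sd standard deviations, minutes.
#' @param nocturnal_exits_rate expected number of nocturnal bed exits per
#'   night (Poisson mean).
#' @param exit_duration_mean mean duration of a nocturnal exit, minutes
#'   (exponential).
#' @param daytime_motion_rate expected motion-sensor triggers per hour while
#'   out of bed.
#' @param quiet_periods optional tibble/data frame with clock-time columns
#'   `start`, `end` (`"HH:MM"`) during which the motion rate is multiplied by
#'   `quiet_rate_factor` (e.g. an afternoon nap in a chair out of view).
#' @param quiet_rate_factor multiplier in \[0, 1\] applied during
#'   `quiet_periods`.
#' @return A `behavior_profile` list.
#' @export
behavior_profile <- function(bed_time_mean = "22:30",
                             bed_time_sd = 30,
                             wake_time_mean = "07:00",
                             wake_time_sd = 30,
                             nocturnal_exits_rate = 1.5,
                             exit_duration_mean = 5,
                             daytime_motion_rate = 8,
                             quiet_periods = NULL,
                             quiet_rate_factor = 0.2) {
  bed_h <- parse_clock_hours(bed_time_mean)
  wake_h <- parse_clock_hours(wake_time_mean)
  # bed times before 02:00 are "after midnight"
  bed_h24 <- if (bed_h < 12) bed_h + 24 else bed_h
  if (bed_h24 < 18 || bed_h24 >= 26) {
    abort("bed_time_mean must lie in [18:00, 02:00)")
  }
  if (wake_h <= 4 || wake_h > 12) {
    abort("wake_time_mean must lie in (04:00, 12:00]")
  }
  stopifnot(bed_time_sd >= 0, wake_time_sd >= 0,
            nocturnal_exits_rate >= 0, exit_duration_mean > 0,
            daytime_motion_rate >= 0,
            quiet_rate_factor >= 0, quiet_rate_factor <= 1)
  if (!is.null(quiet_periods)) {
    quiet_periods <- as_tibble(quiet_periods)
    stopifnot(all(c("start", "end") %in% names(quiet_periods)))
  }
  structure(
    list(bed_time_hours = bed_h24, bed_time_sd = bed_time_sd,
         wake_time_hours = wake_h, wake_time_sd = wake_time_sd,
         nocturnal_exits_rate = nocturnal_exits_rate,
         exit_duration_mean = exit_duration_mean,
         daytime_motion_rate = daytime_motion_rate,
         quiet_periods = quiet_periods,
         quiet_rate_factor = quiet_rate_factor),
    class = "behavior_profile")
}

parse_clock_hours <- function(x) {
  m <- regmatches(x, regexec("^(\\d{1,2}):(\\d{2})$", x))[[1]]
  if (length(m) != 3) abort(paste0("invalid clock time: ", x))
  h <- as.numeric(m[2]) + as.numeric(m[3]) / 60
  if (h < 0 || h >= 24) abort(paste0("invalid clock time: ", x))
  h
}

#' Sensor physics parameters
#'
#' The two deployed-hardware behaviors the simulator reproduces: the PIR
#' motion sensor's post-event dead time, during which further movement is
#' ignored (saves battery and radio traffic), and the usage sensor's
#' minimum registration time — the shortest state change the pressure pad
#' must observe before a `usage_start`/`usage_end` message is sent.
#'
#' @param motion_dead_time dead time in seconds (default 120 = 2 minutes).
#' @param usage_min_registration minimum registration in seconds (default 30).
#' @return A `sensor_physics` list.
#' @export
sensor_physics <- function(motion_dead_time = 120,
                           usage_min_registration = 30) {
  stopifnot(motion_dead_time > 0, usage_min_registration > 0)
  structure(list(motion_dead_time = motion_dead_time,
                 usage_min_registration = usage_min_registration),
            class = "sensor_physics")
}

#' Generate a ground-truth behavior schedule
#'
#' Draws, for each simulated night, a bed interval (normal bed/wake times),
#' nocturnal exit sub-intervals (Poisson count, exponential durations,
#' uniformly placed), and latent motion trigger times: a Poisson process at
#' `daytime_motion_rate` per hour while out of bed and zero while in bed.
#' Latent triggers are pre-sensor truth; pass them through
#' [simulate_motion_events()] to apply the dead time.
#'
#' @param profile a [behavior_profile()].
#' @param n_days number of simulated days (anchored nights).
#' @param seed integer RNG seed; the whole schedule is reproducible from
#'   `(profile, n_days, seed)`.
#' @param start_date first anchor date (the evening of the first night).
#' @param timezone IANA timezone of the simulated home.
#' @param subject_id subject identifier carried into event streams.
#' @return A `gt_schedule` list with tibbles `nights` (`anchor_date`,
#'   `bed_start`, `bed_end`), `exits` (`anchor_date`, `start`, `end`) and
#'   `motion` (`timestamp` of latent triggers), plus the span and metadata.
#' @export
generate_schedule <- function(profile, n_days, seed,
                              start_date = as.Date("2023-03-01"),
                              timezone = "Europe/London",
                              subject_id = "sim-01") {
  stopifnot(inherits(profile, "behavior_profile"), n_days >= 1)
  set.seed(as.integer(seed))
  start_date <- as.Date(start_date)
  anchor_dates <- start_date + seq_len(n_days) - 1L
  midnights <- as.POSIXct(paste(anchor_dates, "00:00:00"), tz = timezone)

  bed_start <- midnights +
    round((profile$bed_time_hours +
             rnorm(n_days, 0, profile$bed_time_sd / 60)) * 3600)
  bed_end <- midnights + 86400 +
    round((profile$wake_time_hours +
             rnorm(n_days, 0, profile$wake_time_sd / 60)) * 3600)
  # guard against pathological draws inverting the night
  bed_end <- pmax(bed_end, bed_start + 3600)
  nights <- tibble(anchor_date = anchor_dates,
                   bed_start = bed_start, bed_end = bed_end)

  exits <- draw_exits(nights, profile$nocturnal_exits_rate,
                      profile$exit_duration_mean)

  span_start <- as.POSIXct(paste(start_date, "12:00:00"), tz = timezone)
  span_end <- as.POSIXct(paste(start_date + n_days, "12:00:00"),
                         tz = timezone)
  sched <- structure(
    list(nights = nights, exits = exits,
         motion = tibble(timestamp = as.POSIXct(character(), tz = timezone)),
         span_start = span_start, span_end = span_end,
         timezone = timezone, subject_id = subject_id, profile = profile),
    class = "gt_schedule")
  sched$motion <- draw_motion(sched, schedule_out_of_bed(sched))
  sched
}

# Poisson number of exits per night, exponential durations, uniform placement
# inside the bed interval; overlapping draws are dropped (first wins).
draw_exits <- function(nights, rate, dur_mean) {
  tz <- attr(nights$bed_start, "tzone")
  out <- list()
  for (i in seq_len(nrow(nights))) {
    k <- rpois(1, rate)
    if (k == 0) next
    len <- as.numeric(nights$bed_end[i] - nights$bed_start[i], units = "secs")
    dur <- round(rexp(k, 1 / (dur_mean * 60)))
    dur <- pmax(dur, 1)
    s <- round(runif(k, 0, pmax(len - dur, 0)))
    st <- nights$bed_start[i] + s
    en <- pmin(st + dur, nights$bed_end[i])
    ord <- order(st)
    st <- st[ord]; en <- en[ord]
    keep <- rep(TRUE, k)
    last_end <- nights$bed_start[i]
    for (j in seq_len(k)) {
      if (st[j] < last_end || en[j] <= st[j]) {
        keep[j] <- FALSE
      } else {
        last_end <- en[j]
      }
    }
    if (any(keep)) {
      out[[length(out) + 1L]] <- tibble(
        anchor_date = nights$anchor_date[i],
        start = st[keep], end = en[keep])
    }
  }
  if (length(out) == 0) {
    return(tibble(anchor_date = as.Date(character()),
                  start = as.POSIXct(character(), tz = tz),
                  end = as.POSIXct(character(), tz = tz)))
  }
  dplyr::bind_rows(out)
}

# Homogeneous Poisson draw on each out-of-bed span, thinned inside quiet
# clock-time periods.
draw_motion <- function(sched, spans) {
  profile <- sched$profile
  rate_s <- profile$daytime_motion_rate / 3600
  times <- numeric(0)
  if (rate_s > 0 && nrow(spans) > 0) {
    for (i in seq_len(nrow(spans))) {
      len <- as.numeric(spans$end[i] - spans$start[i], units = "secs")
      if (len <= 0) next
      k <- rpois(1, rate_s * len)
      if (k > 0) {
        times <- c(times, as.numeric(spans$start[i]) + sort(runif(k, 0, len)))
      }
    }
  }
  ts <- as.POSIXct(round(times), tz = sched$timezone,
                   origin = "1970-01-01")
  if (!is.null(profile$quiet_periods) && length(ts) > 0) {
    h <- clock_hours(ts)
    in_quiet <- rep(FALSE, length(ts))
    for (i in seq_len(nrow(profile$quiet_periods))) {
      qs <- parse_clock_hours(profile$quiet_periods$start[i])
      qe <- parse_clock_hours(profile$quiet_periods$end[i])
      in_quiet <- in_quiet | (h >= qs & h < qe)
    }
    keep <- !in_quiet | (runif(length(ts)) < profile$quiet_rate_factor)
    ts <- ts[keep]
  }
  tibble(timestamp = sort(ts))
}

clock_hours <- function(ts) {
  lt <- as.POSIXlt(ts)
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' Ground-truth occupancy and out-of-bed spans of a schedule
#'
#' `schedule_occupancy()` returns the true in-bed intervals (bed interval
#' minus nocturnal exits); `schedule_out_of_bed()` their complement within
#' the simulated span.
#'
#' @param schedule a `gt_schedule`.
#' @return Tibble with columns `start`, `end`.
#' @export
schedule_occupancy <- function(schedule) {
  stopifnot(inherits(schedule, "gt_schedule"))
  tz <- schedule$timezone
  out <- list()
  for (i in seq_len(nrow(schedule$nights))) {
    bs <- schedule$nights$bed_start[i]
    be <- schedule$nights$bed_end[i]
    ex <- dplyr::filter(schedule$exits,
                        .data$anchor_date == schedule$nights$anchor_date[i])
    cur <- bs
    if (nrow(ex) > 0) {
      for (j in seq_len(nrow(ex))) {
        if (ex$start[j] > cur) {
          out[[length(out) + 1L]] <- tibble(start = cur, end = ex$start[j])
        }
        cur <- ex$end[j]
      }
    }
    if (be > cur) {
      out[[length(out) + 1L]] <- tibble(start = cur, end = be)
    }
  }
  if (length(out) == 0) {
    return(tibble(start = as.POSIXct(character(), tz = tz),
                  end = as.POSIXct(character(), tz = tz)))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start)
}

#' @rdname schedule_occupancy
#' @export
schedule_out_of_bed <- function(schedule) {
  occ <- schedule_occupancy(schedule)
  complement_intervals(occ, schedule$span_start, schedule$span_end)
}

complement_intervals <- function(intervals, span_start, span_end) {
  tz <- attr(span_start, "tzone")
  if (nrow(intervals) == 0) {
    return(tibble(start = span_start, end = span_end))
  }
  iv <- dplyr::arrange(intervals, .data$start)
  starts <- c(span_start, iv$end)
  ends <- c(iv$start, span_end)
  keep <- ends > starts & ends > span_start & starts < span_end
  tibble(start = pmax(starts[keep], span_start),
         end = pmin(ends[keep], span_end))
}

#' Simulate motion-sensor events from a schedule
#'
#' Applies the PIR dead-time model to the schedule's latent trigger times:
#' the first trigger is emitted, then every latent trigger within
#' `motion_dead_time` of the last *emitted* event is suppressed
#' (non-retriggerable hold-off). Emitted inter-event gaps are therefore
#' always at least the dead time.
#'
#' @param schedule a `gt_schedule`.
#' @param physics a [sensor_physics()].
#' @param sensor_id identifier for the emitting sensor.
#' @return An event-stream tibble of `motion` events.
#' @export
simulate_motion_events <- function(schedule, physics = sensor_physics(),
                                   sensor_id = "pir-1") {
  stopifnot(inherits(schedule, "gt_schedule"),
            inherits(physics, "sensor_physics"))
  emitted <- apply_dead_time(schedule$motion$timestamp,
                             physics$motion_dead_time)
  event_stream(timestamp = emitted,
               subject_id = rep(schedule$subject_id, length(emitted)),
               sensor_id = rep(sensor_id, length(emitted)),
               sensor_type = rep("motion", length(emitted)),
               event_kind = rep("motion", length(emitted)))
}

#' Apply a non-retriggerable dead time to trigger times
#'
#' Emits the first trigger, then suppresses triggers strictly closer than
#' `dead_time` seconds to the last emitted one. A trigger exactly
#' `dead_time` after the last emission is emitted.
#'
#' @param times sorted POSIXct (or numeric seconds) trigger times.
#' @param dead_time hold-off in seconds.
#' @return The emitted subset of `times`.
#' @export
apply_dead_time <- function(times, dead_time) {
  times <- sort(times)
  n <- length(times)
  if (n == 0) return(times)
  keep <- logical(n)
  keep[1] <- TRUE
  last <- as.numeric(times[1])
  tn <- as.numeric(times)
  for (i in seq_len(n)[-1]) {
    if (tn[i] - last >= dead_time) {
      keep[i] <- TRUE
      last <- tn[i]
    }
  }
  times[keep]
}

#' Apply the usage sensor's minimum-registration debounce to occupancy states
#'
#' The pressure pad only reports a state change once the new state has
#' persisted for `min_registration` seconds. Modelled as state smoothing
#' before emission: first, vacancy gaps shorter than the threshold are merged
#' into the surrounding occupancy; then occupancy spells still shorter than
#' the threshold are dropped. A state lasting exactly the threshold is
#' registered (the minimum is inclusive). Because smoothing precedes
#' emission, no orphan start/end pairs are produced.
#'
#' @param intervals tibble of true occupancy intervals (`start`, `end`),
#'   sorted, non-overlapping.
#' @param min_registration threshold in seconds.
#' @return Tibble of registered occupancy intervals (`start`, `end`).
#' @export
apply_usage_registration <- function(intervals, min_registration) {
  iv <- dplyr::arrange(as_tibble(intervals), .data$start)
  if (nrow(iv) == 0) return(iv[c("start", "end")])
  # merge sub-threshold vacancies
  starts <- as.numeric(iv$start)
  ends <- as.numeric(iv$end)
  ms <- starts[1]; me <- ends[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(iv))[-1]) {
    if (starts[i] - me < min_registration) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  # drop sub-threshold occupancies
  keep <- (out_e - out_s) >= min_registration
  tz <- attr(iv$start, "tzone")
  tibble(
    start = as.POSIXct(out_s[keep], tz = tz, origin = "1970-01-01"),
    end = as.POSIXct(out_e[keep], tz = tz, origin = "1970-01-01"))
}

#' Simulate usage-sensor events from a schedule
#'
#' Derives the true occupancy states (bed interval minus exits), applies the
#' minimum-registration debounce via [apply_usage_registration()], and emits
#' alternating `usage_start`/`usage_end` events at the true transition times
#' of the surviving states.
#'
#' @inheritParams simulate_motion_events
#' @export
simulate_usage_events <- function(schedule, physics = sensor_physics(),
                                  sensor_id = "bed-1") {
  stopifnot(inherits(schedule, "gt_schedule"),
            inherits(physics, "sensor_physics"))
  occ <- schedule_occupancy(schedule)
  reg <- apply_usage_registration(occ, physics$usage_min_registration)
  n <- nrow(reg)
  ts <- as.POSIXct(as.vector(rbind(as.numeric(reg$start),
                                   as.numeric(reg$end))),
                   tz = schedule$timezone, origin = "1970-01-01")
  event_stream(
    timestamp = ts,
    subject_id = rep(schedule$subject_id, 2 * n),
    sensor_id = rep(sensor_id, 2 * n),
    sensor_type = rep("usage", 2 * n),
    event_kind = rep(c("usage_start", "usage_end"), n))
}

#' Simulate both sensors and combine into one stream
#'
#' @inheritParams simulate_motion_events
#' @param motion_sensor_id,usage_sensor_id sensor identifiers.
#' @return A combined, sorted event-stream tibble.
#' @export
simulate_events <- function(schedule, physics = sensor_physics(),
                            motion_sensor_id = "pir-1",
                            usage_sensor_id = "bed-1") {
  validate_event_stream(dplyr::bind_rows(
    simulate_motion_events(schedule, physics, motion_sensor_id),
    simulate_usage_events(schedule, physics, usage_sensor_id)))
}

#' Inject a behavioral anomaly into a ground-truth schedule
#'
#' Modifies only the targeted anchor dates, leaving all other days
#' bit-identical, so feature-recovery tests can check that downstream
#' features move in the right direction on exactly those dates.
#'
#' Kinds:
#' \describe{
#'   \item{`delayed_bedtime`}{bed start shifted later by `magnitude` minutes;
#'     exits falling before the new bed start are dropped; latent motion is
#'     added in the newly out-of-bed evening window.}
#'   \item{`increased_exits`}{nocturnal exits on the targeted nights are
#'     redrawn with the exit rate multiplied by `magnitude`; latent motion
#'     inside the targeted bed intervals is regenerated to match the new
#'     exits.}
#'   \item{`reduced_daytime_activity`}{latent motion triggers on the targeted
#'     calendar dates are thinned, each kept with probability `magnitude`.}
#' }
#'
#' @param schedule a `gt_schedule`.
#' @param kind one of `"delayed_bedtime"`, `"increased_exits"`,
#'   `"reduced_daytime_activity"`.
#' @param dates Date vector of targeted anchor dates.
#' @param magnitude kind-specific amount (minutes for `delayed_bedtime`,
#'   rate multiplier for `increased_exits`, keep-probability for
#'   `reduced_daytime_activity`).
#' @param seed RNG seed for the stochastic kinds.
#' @return The modified `gt_schedule`.
#' @export
inject_anomaly <- function(schedule, kind, dates, magnitude, seed = 1) {
  stopifnot(inherits(schedule, "gt_schedule"))
  kind <- match.arg(kind, c("delayed_bedtime", "increased_exits",
                            "reduced_daytime_activity"))
  dates <- as.Date(dates)
  if (length(dates) == 0) abort("empty date range")
  if (!all(dates %in% schedule$nights$anchor_date)) {
    abort("targeted dates must lie within the schedule span")
  }
  set.seed(as.integer(seed))
  sc <- schedule
  tgt <- sc$nights$anchor_date %in% dates
  if (kind == "delayed_bedtime") {
    old_start <- sc$nights$bed_start[tgt]
    sc$nights$bed_start[tgt] <- old_start + round(magnitude * 60)
    sc$nights$bed_end[tgt] <- pmax(sc$nights$bed_end[tgt],
                                   sc$nights$bed_start[tgt] + 3600)
    # exits now outside the bed interval are dropped/clipped
    keep <- rep(TRUE, nrow(sc$exits))
    for (i in seq_len(nrow(sc$exits))) {
      d <- sc$exits$anchor_date[i]
      if (!d %in% dates) next
      bs <- sc$nights$bed_start[sc$nights$anchor_date == d]
      if (sc$exits$end[i] <= bs) {
        keep[i] <- FALSE
      } else if (sc$exits$start[i] < bs) {
        sc$exits$start[i] <- bs
      }
    }
    sc$exits <- sc$exits[keep, ]
    # newly out-of-bed evening windows gain latent motion
    new_spans <- tibble(start = old_start,
                        end = sc$nights$bed_start[tgt])
    extra <- draw_motion(sc, new_spans)
    sc$motion <- dplyr::arrange(dplyr::bind_rows(sc$motion, extra),
                                .data$timestamp)
  } else if (kind == "increased_exits") {
    rate <- sc$profile$nocturnal_exits_rate * magnitude
    nights_tgt <- sc$nights[tgt, ]
    # drop old exits and their latent motion within the targeted beds
    sc$exits <- dplyr::filter(sc$exits, !.data$anchor_date %in% dates)
    in_bed <- rep(FALSE, nrow(sc$motion))
    for (i in seq_len(nrow(nights_tgt))) {
      in_bed <- in_bed | (sc$motion$timestamp >= nights_tgt$bed_start[i] &
                            sc$motion$timestamp < nights_tgt$bed_end[i])
    }
    sc$motion <- sc$motion[!in_bed, ]
    new_exits <- draw_exits(nights_tgt, rate, sc$profile$exit_duration_mean)
    sc$exits <- dplyr::arrange(dplyr::bind_rows(sc$exits, new_exits),
                               .data$start)
    if (nrow(new_exits) > 0) {
      extra <- draw_motion(sc, dplyr::select(new_exits, "start", "end"))
      sc$motion <- dplyr::bind_rows(sc$motion, extra)
    }
    sc$motion <- dplyr::arrange(sc$motion, .data$timestamp)
  } else { # reduced_daytime_activity
    stopifnot(magnitude >= 0, magnitude <= 1)
    on_day <- as.Date(format(sc$motion$timestamp, "%Y-%m-%d")) %in% dates
    drop <- on_day & runif(nrow(sc$motion)) >= magnitude
    sc$motion <- sc$motion[!drop, ]
  }
  sc
}
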