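# Small builders for hand-specified fixtures; all computed in code.

TZ <- "Europe/London"

pt <- function(x, tz = TZ) as.POSIXct(x, tz = tz)

mk_motion_stream <- function(times, tz = TZ, subject = "s1", sensor = "pir-1") {
  times <- if (inherits(times, "POSIXct")) times else pt(times, tz)
  event_stream(timestamp = times,
               subject_id = rep(subject, length(times)),
               sensor_id = rep(sensor, length(times)),
               sensor_type = rep("motion", length(times)),
               event_kind = rep("motion", length(times)))
}

mk_usage_stream <- function(starts, ends, tz = TZ, subject = "s1",
                            sensor = "bed-1") {
  starts <- if (inherits(starts, "POSIXct")) starts else pt(starts, tz)
  ends <- if (inherits(ends, "POSIXct")) ends else pt(ends, tz)
  event_stream(
    timestamp = c(starts, ends),
    subject_id = rep(subject, length(starts) + length(ends)),
    sensor_id = rep(sensor, length(starts) + length(ends)),
    sensor_type = rep("usage", length(starts) + length(ends)),
    event_kind = c(rep("usage_start", length(starts)),
                   rep("usage_end", length(ends))))
}

mk_intervals <- function(starts, ends, tz = TZ) {
  tibble::tibble(
    start = if (inherits(starts, "POSIXct")) starts else pt(starts, tz),
    end = if (inherits(ends, "POSIXct")) ends else pt(ends, tz))
}

rand_stream <- function(n = 20, tz = TZ, subject = "s1") {
  base <- pt("2023-03-01 00:00:00", tz)
  n_m <- ceiling(n / 2)
  n_u <- floor(n / 4)
  motion <- base + sort(sample.int(7 * 86400, n_m))
  us <- base + sort(sample.int(7 * 86400, 2 * n_u))
  ev <- dplyr::bind_rows(
    mk_motion_stream(motion, tz, subject),
    if (n_u > 0) mk_usage_stream(us[seq(1, 2 * n_u, 2)],
                                 us[seq(2, 2 * n_u, 2)], tz, subject))
  validate_event_stream(ev)
}
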