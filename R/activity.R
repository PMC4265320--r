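#' Gaussian kernel parameters for the activity function
#'
#' The continuous activity function is the convolution of unit-weight event
#' impulses with a normal (Gaussian) kernel of standard deviation `sigma`,
#' truncated at `truncation_multiple` sigma. With the defaults (sigma = 15
#' minutes, truncation at 3 sigma) the truncated kernel retains about 99.7%
#' of its mass; it is deliberately *not* renormalized after truncation, so
#' the function's integral slightly under-counts events (by at most 0.3%).
#'
#' @param sigma kernel standard deviation, minutes.
#' @param truncation_multiple kernel support half-width in units of sigma.
#' @param resolution sampling step of the output grid, minutes; must not
#'   exceed `sigma`. The 1-minute default matches the information content of
#'   a sensor with a 2-minute dead time.
#' @return A `kernel_params` list.
#' @export
kernel_params <- function(sigma = 15, truncation_multiple = 3,
                          resolution = 1) {
  stopifnot(sigma > 0, truncation_multiple > 0, resolution > 0)
  if (resolution > sigma) abort("resolution must not exceed sigma")
  structure(list(sigma = sigma, truncation_multiple = truncation_multiple,
                 resolution = resolution),
            class = "kernel_params")
}

#' Continuous activity function from motion events
#'
#' Represents the motion events as unit-weight impulses and convolves them
#' with the truncated Gaussian kernel, sampling on a regular grid across
#' `span`. The value at grid time t is `sum over events of K(t - t_event)`
#' with K the unit-area normal density (per-minute units), set to zero
#' beyond `truncation_multiple * sigma`; K is not renormalized after
#' truncation. Units are events per minute, so the function integrates to
#' (approximately) the event count.
#'
#' @param events event-stream tibble; only `motion` events are used.
#' @param params a [kernel_params()].
#' @param span POSIXct length-2 vector `c(start, end)` of the output grid.
#'   Should extend `truncation_multiple * sigma` beyond the events of
#'   interest; if events fall closer than that to an edge a warning flags
#'   possible edge effects.
#' @return Tibble with columns `time` (POSIXct grid) and `activity`
#'   (events/minute).
#' @examples
#' tz <- "Europe/London"
#' es <- event_stream(as.POSIXct("2023-03-01 12:00:00", tz = tz),
#'                    "s1", "pir-1", "motion", "motion")
#' af <- activity_function(es, kernel_params(),
#'   span = as.POSIXct(c("2023-03-01 10:00", "2023-03-01 14:00"), tz = tz))
#' max(af$activity) # ~ 1 / (15 * sqrt(2*pi)) = 0.0266 events/min
#' @export
activity_function <- function(events, params = kernel_params(), span) {
  stopifnot(inherits(params, "kernel_params"), length(span) == 2,
            inherits(span, "POSIXct"), span[2] > span[1])
  ev <- validate_event_stream(events)
  ev <- dplyr::filter(ev, .data$event_kind == "motion",
                      .data$timestamp >= span[1],
                      .data$timestamp <= span[2])
  res_s <- params$resolution * 60
  sigma_s <- params$sigma * 60
  half_s <- params$truncation_multiple * sigma_s
  grid_n <- floor(as.numeric(span[2] - span[1], units = "secs") / res_s)
  grid <- span[1] + seq(0, grid_n) * res_s
  values <- numeric(length(grid))
  if (nrow(ev) > 0) {
    te <- as.numeric(ev$timestamp)
    if (any(te - as.numeric(span[1]) < half_s) ||
        any(as.numeric(span[2]) - te < half_s)) {
      warn("events within one truncation width of the span edge: activity near the edges is attenuated")
    }
    tg <- as.numeric(grid)
    # per-event local window: kernel support is +/- half_s
    for (i in seq_along(te)) {
      lo <- max(1L, ceiling((te[i] - half_s - tg[1]) / res_s) + 1L)
      hi <- min(length(tg), floor((te[i] + half_s - tg[1]) / res_s) + 1L)
      if (lo > hi) next
      d_min <- (tg[lo:hi] - te[i]) / 60
      values[lo:hi] <- values[lo:hi] + dnorm(d_min, sd = params$sigma)
    }
  }
  tibble(time = grid, activity = values)
}

#' Day-part counting windows
#'
#' The three clock-of-day windows used to summarise a 24-hour period:
#' early morning and waking \[06:00, 10:00), daytime activity
#' \[10:00, 22:00) and nighttime \[22:00, 06:00 next day). They partition the
#' 24-hour day exactly (4 + 12 + 8 = 24 h); all bins are half-open.
#'
#' @param morning_start,daytime_start,nighttime_start boundary clock times
#'   (`"HH:MM"`).
#' @return A `day_part_windows` list of boundary hours.
#' @export
day_part_windows <- function(morning_start = "06:00",
                             daytime_start = "10:00",
                             nighttime_start = "22:00") {
  m <- parse_clock_hours(morning_start)
  d <- parse_clock_hours(daytime_start)
  n <- parse_clock_hours(nighttime_start)
  if (!(m < d && d < n)) {
    abort("day-part boundaries must be ordered morning < daytime < nighttime")
  }
  structure(list(morning_start = m, daytime_start = d, nighttime_start = n),
            class = "day_part_windows")
}

#' Hourly motion-event counts for one civil date
#'
#' Counts motion events in the 24 half-open hour bins \[h:00, h+1:00) of the
#' given civil date.
#'
#' @param events event-stream tibble.
#' @param date civil date (Date or coercible).
#' @return Tibble with columns `date`, `hour` (0-23) and `count`.
#' @export
hourly_counts <- function(events, date) {
  ev <- validate_event_stream(events)
  date <- as.Date(date)
  ev <- dplyr::filter(ev, .data$event_kind == "motion")
  tz <- attr(ev$timestamp, "tzone") %||% "UTC"
  day0 <- as.POSIXct(paste(date, "00:00:00"), tz = tz)
  day1 <- as.POSIXct(paste(date + 1, "00:00:00"), tz = tz)
  ts <- ev$timestamp[ev$timestamp >= day0 & ev$timestamp < day1]
  hours <- as.POSIXlt(ts)$hour
  counts <- tabulate(hours + 1L, nbins = 24L)
  tibble(date = date, hour = 0:23, count = as.integer(counts))
}

#' Day-part motion-event counts for one anchored day
#'
#' Counts motion events in the three day-part windows. The nighttime window
#' of anchor date D is \[D 22:00, D+1 06:00): the night is attributed to the
#' evening's date, matching how clinicians speak of "the night of day D".
#' The day being counted therefore spans \[D 06:00, D+1 06:00) and the three
#' counts partition its events.
#'
#' @param events event-stream tibble.
#' @param date anchor civil date.
#' @param windows a [day_part_windows()].
#' @return One-row tibble with `date`, `morning_count`, `daytime_count`,
#'   `nighttime_count`.
#' @export
day_part_counts <- function(events, date, windows = day_part_windows()) {
  stopifnot(inherits(windows, "day_part_windows"))
  ev <- validate_event_stream(events)
  date <- as.Date(date)
  ev <- dplyr::filter(ev, .data$event_kind == "motion")
  tz <- attr(ev$timestamp, "tzone") %||% "UTC"
  at <- function(d, hours) {
    h <- floor(hours)
    m <- round((hours - h) * 60)
    as.POSIXct(sprintf("%s %02d:%02d:00", d, h, m), tz = tz)
  }
  n_in <- function(a, b) sum(ev$timestamp >= a & ev$timestamp < b)
  tibble(
    date = date,
    morning_count = n_in(at(date, windows$morning_start),
                         at(date, windows$daytime_start)),
    daytime_count = n_in(at(date, windows$daytime_start),
                         at(date, windows$nighttime_start)),
    nighttime_count = n_in(at(date, windows$nighttime_start),
                           at(date + 1, windows$morning_start))
  )
}
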