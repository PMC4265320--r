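#' Night analysis window
#'
#' Every per-night feature is computed inside a fixed 18-hour window anchored
#' on the evening's civil date: from 18:00 of the anchor date to 12:00 of the
#' next day. The first time in bed is searched after 18:00, the last time out
#' of bed before 12:00. Nights are indexed by their anchor (evening) date
#' everywhere in the package.
#'
#' @param anchor_date civil date of the evening the night starts on.
#' @param timezone IANA timezone.
#' @return A `night_window` list with `anchor_date`, `start`, `end` and the
#'   night-core bounds (22:00 to 06:00) used by the inactivity search.
#' @export
night_window <- function(anchor_date, timezone = "Europe/London") {
  anchor_date <- as.Date(anchor_date)
  at <- function(d, hm) as.POSIXct(paste(d, hm), tz = timezone)
  structure(
    list(anchor_date = anchor_date,
         start = at(anchor_date, "18:00:00"),
         end = at(anchor_date + 1, "12:00:00"),
         core_start = at(anchor_date, "22:00:00"),
         core_end = at(anchor_date + 1, "06:00:00")),
    class = "night_window")
}

# Clip occupancy intervals to a window; integer-second arithmetic.
clip_intervals <- function(intervals, w_start, w_end) {
  iv <- dplyr::filter(as_tibble(intervals),
                      .data$end > w_start, .data$start < w_end)
  if (nrow(iv) == 0) return(iv)
  truncated <- iv$start < w_start | iv$end > w_end
  iv$start <- pmax(iv$start, w_start)
  iv$end <- pmin(iv$end, w_end)
  iv$truncated <- truncated
  dplyr::arrange(iv, .data$start)
}

empty_usage_row <- function(window, reason) {
  na_t <- as.POSIXct(NA, tz = attr(window$start, "tzone"))
  tibble(anchor_date = window$anchor_date,
         time_in_bed = na_t, time_out_of_bed = na_t, mean_time = na_t,
         time_in_bed_h = NA_real_, time_out_of_bed_h = NA_real_,
         mean_time_h = NA_real_,
         total_period_in_bed = 0L, accumulated_period_in_bed = 0L,
         accumulated_period_out_of_bed = 0L, continuity = NA_real_,
         window_truncated = FALSE, usage_reason = reason)
}

#' Per-night usage-sensor features
#'
#' Computes the night's bed-usage feature set from paired occupancy
#' intervals clipped to the night window:
#' \describe{
#'   \item{time_in_bed}{start of the first occupancy at/after 18:00 (an
#'     interval already in progress at 18:00 counts, with time_in_bed =
#'     18:00 and `window_truncated = TRUE`);}
#'   \item{time_out_of_bed}{end of the last occupancy at/before next-day
#'     12:00;}
#'   \item{total_period_in_bed}{time_out_of_bed minus time_in_bed, seconds;}
#'   \item{accumulated_period_in_bed}{sum of occupied spans (a.k.a.
#'     occupancy), seconds;}
#'   \item{accumulated_period_out_of_bed}{unoccupied time between
#'     time_in_bed and time_out_of_bed, seconds;}
#'   \item{continuity}{accumulated in-bed time / total period, in (0, 1\];
#'     1 means an uninterrupted night;}
#'   \item{mean_time}{occupancy-weighted mean timestamp (centroid of in-bed
#'     time, computed on an 18:00-anchored axis so midnight wraparound
#'     cannot bite); always lies in \[time_in_bed, time_out_of_bed\].}
#' }
#' Clock features are also reported as decimal hours since 18:00
#' (`*_h` columns) for plotting. Durations are exact integer seconds, so
#' `accumulated_in + accumulated_out == total_period` holds exactly.
#'
#' @param intervals occupancy-interval tibble (`start`, `end`), e.g. from
#'   [pair_occupancy()]; sorted, non-overlapping.
#' @param window a [night_window()].
#' @return One-row tibble; when no interval falls in the window all time
#'   features are `NA` with `usage_reason = "no_usage_events"`.
#' @export
extract_usage_features <- function(intervals, window) {
  stopifnot(inherits(window, "night_window"))
  iv <- clip_intervals(intervals, window$start, window$end)
  if (nrow(iv) == 0) {
    return(empty_usage_row(window, "no_usage_events"))
  }
  secs <- function(x) as.integer(round(as.numeric(
    x - window$start, units = "secs")))
  s <- secs(iv$start)
  e <- secs(iv$end)
  time_in <- iv$start[1]
  time_out <- iv$end[nrow(iv)]
  total <- e[length(e)] - s[1]
  acc_in <- sum(e - s)
  acc_out <- total - acc_in
  lens <- as.numeric(e - s)
  centroid <- sum(lens * (as.numeric(s) + e) / 2) / sum(lens)
  mean_time <- window$start + centroid
  tibble(
    anchor_date = window$anchor_date,
    time_in_bed = time_in, time_out_of_bed = time_out, mean_time = mean_time,
    time_in_bed_h = s[1] / 3600 + 18,
    time_out_of_bed_h = e[length(e)] / 3600 + 18,
    mean_time_h = centroid / 3600 + 18,
    total_period_in_bed = as.integer(total),
    accumulated_period_in_bed = as.integer(acc_in),
    accumulated_period_out_of_bed = as.integer(acc_out),
    continuity = acc_in / total,
    window_truncated = any(iv$truncated),
    usage_reason = NA_character_)
}

empty_motion_row <- function(window, reason) {
  na_t <- as.POSIXct(NA, tz = attr(window$start, "tzone"))
  tibble(anchor_date = window$anchor_date,
         start_of_inactivity = na_t, end_of_inactivity = na_t,
         mean_time_of_inactivity = na_t,
         duration_of_inactivity = 0L,
         inactivity_censored_start = FALSE,
         inactivity_censored_end = FALSE,
         motion_reason = reason)
}

#' Per-night motion-sensor nocturnal inactivity features
#'
#' When no bed sensor is available, the sleep period is proxied by nocturnal
#' inactivity: the longest motion-free gap that intersects the night core
#' (22:00-06:00) and lasts at least `min_gap`. The start of inactivity is the
#' time activity ceased in the evening (the event opening the gap), the end
#' is the first activity in the morning (the event closing it); the mean time
#' is their midpoint and the duration their difference. A gap touching the
#' window edge uses the window boundary as a censored endpoint and is
#' flagged.
#'
#' @param events event-stream tibble (motion events are selected).
#' @param window a [night_window()].
#' @param min_gap minimum qualifying gap, seconds (default 3 hours).
#' @return One-row tibble; `motion_reason` is `"no_motion_events"` or
#'   `"no_qualifying_gap"` when the features are undefined.
#' @export
extract_motion_inactivity <- function(events, window, min_gap = 3 * 3600) {
  stopifnot(inherits(window, "night_window"))
  ev <- validate_event_stream(events)
  ts <- ev$timestamp[ev$event_kind == "motion" &
                       ev$timestamp >= window$start &
                       ev$timestamp <= window$end]
  if (length(ts) == 0) {
    return(empty_motion_row(window, "no_motion_events"))
  }
  ts <- sort(ts)
  gap_start <- c(window$start, ts)
  gap_end <- c(ts, window$end)
  cens_start <- c(TRUE, rep(FALSE, length(ts)))
  cens_end <- c(rep(FALSE, length(ts)), TRUE)
  len <- as.numeric(gap_end - gap_start, units = "secs")
  qualifies <- len >= min_gap &
    gap_start < window$core_end & gap_end > window$core_start
  if (!any(qualifies)) {
    return(empty_motion_row(window, "no_qualifying_gap"))
  }
  best <- which(qualifies)[which.max(len[qualifies])]
  s <- gap_start[best]; e <- gap_end[best]
  tibble(
    anchor_date = window$anchor_date,
    start_of_inactivity = s, end_of_inactivity = e,
    mean_time_of_inactivity = s + as.numeric(e - s, units = "secs") / 2,
    duration_of_inactivity = as.integer(round(
      as.numeric(e - s, units = "secs"))),
    inactivity_censored_start = cens_start[best],
    inactivity_censored_end = cens_end[best],
    motion_reason = NA_character_)
}

#' Nightly feature table
#'
#' Runs occupancy pairing once over the stream, then extracts the usage and
#' motion-inactivity feature sets for every anchor date in `dates`. Nights
#' with no data are present with reason codes, never silently dropped. If a
#' night window contains usage events but no paired interval, the usage
#' reason is `"unpaired_only"`.
#'
#' @param events event-stream tibble.
#' @param dates Date vector of anchor dates (one row each).
#' @param min_gap minimum qualifying inactivity gap, seconds.
#' @return Tibble with one row per anchor date joining both feature sets.
#' @export
nightly_feature_table <- function(events, dates, min_gap = 3 * 3600) {
  dates <- as.Date(dates)
  if (length(dates) == 0) abort("empty date range")
  ev <- validate_event_stream(events)
  tz <- attr(ev$timestamp, "tzone") %||% "Europe/London"
  intervals <- suppressWarnings(pair_occupancy(ev))
  purrr::map_dfr(dates, function(d) {
    w <- night_window(d, timezone = tz)
    u <- extract_usage_features(intervals, w)
    if (!is.na(u$usage_reason) && u$usage_reason == "no_usage_events") {
      has_usage <- any(ev$sensor_type == "usage" &
                         ev$timestamp >= w$start & ev$timestamp <= w$end)
      if (has_usage) u$usage_reason <- "unpaired_only"
    }
    m <- extract_motion_inactivity(ev, w, min_gap = min_gap)
    dplyr::left_join(u, m, by = "anchor_date")
  })
}
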