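#' Rendering configuration
#'
#' Final-cycle colour semantics, kept as overridable defaults: actual data
#' blue, usual pattern dark grey, in-bed green, out-of-bed red. One feature
#' per panel; dates (not study-day numbers) on horizontal axes.
#'
#' @param actual,pattern,in_bed,out_of_bed colour values.
#' @param format output image format, `"png"` or `"svg"`.
#' @param width,height,dpi device size (inches) and resolution.
#' @return A `render_config` list.
#' @export
render_config <- function(actual = "#1f77b4", pattern = "grey25",
                          in_bed = "forestgreen", out_of_bed = "firebrick",
                          format = "png", width = 8, height = 4.5,
                          dpi = 120) {
  stopifnot(format %in% c("png", "svg"))
  structure(list(actual = actual, pattern = pattern, in_bed = in_bed,
                 out_of_bed = out_of_bed, format = format,
                 width = width, height = height, dpi = dpi),
            class = "render_config")
}

#' Implemented visualization catalogue
#'
#' Identifiers of the clinician-preferred final views the package renders:
#' \tabular{ll}{
#'   1.2 \tab 24 h usage timeline, actual data only \cr
#'   1.3 \tab 24 h usage timeline with usual pattern superimposed \cr
#'   2.4 \tab 24 h motion events/hour bars with usual pattern \cr
#'   2.5 \tab 24 h motion events/hour, difference from usual pattern \cr
#'   3.1 \tab days: in-bed / out-of-bed hours, points + running average \cr
#'   3.6 \tab days: stacked areas of running-average in/out-of-bed hours \cr
#'   4.1 \tab days: usage event counts \cr
#'   5.1 \tab raw usage occupancy day strips \cr
#'   6.1 \tab days: nocturnal inactivity start/end times \cr
#'   6.2 \tab days: nocturnal inactivity hours \cr
#'   7.1 \tab days: motion event counts \cr
#'   7.2 \tab days: motion event counts per day part \cr
#' }
#' @return Character vector of view identifiers.
#' @export
implemented_views <- function() {
  c("1.2", "1.3", "2.4", "2.5", "3.1", "3.6", "4.1", "5.1",
    "6.1", "6.2", "7.1", "7.2")
}

#' Rasterize occupancy or activity into a day-strip matrix
#'
#' Builds the 1440 x n_days matrix behind the day-strip views: each column
#' is one date, each row one minute of the day (00:00 at row 1). For
#' occupancy intervals (`start`/`end` columns) a cell is 1 when the minute's
#' starting instant lies inside an interval, so total ones equal the total
#' minute count of (minute-aligned) intervals, with intervals crossing
#' midnight split across adjacent columns without gap or double-count. For
#' an activity function (`time`/`activity` columns) cells carry the sampled
#' activity level.
#'
#' @param x occupancy intervals (`start`, `end`) or an activity-function
#'   tibble (`time`, `activity`).
#' @param dates Date vector (one column each).
#' @param timezone timezone used to anchor each date's minute grid; defaults
#'   to the data's timezone.
#' @return Numeric matrix, 1440 rows x `length(dates)` columns.
#' @export
build_day_strip_matrix <- function(x, dates, timezone = NULL) {
  dates <- as.Date(dates)
  if (length(dates) == 0) abort("empty dates")
  x <- as_tibble(x)
  is_intervals <- all(c("start", "end") %in% names(x))
  is_activity <- all(c("time", "activity") %in% names(x))
  if (!is_intervals && !is_activity) {
    abort("x must have start/end (occupancy) or time/activity columns")
  }
  tcol <- if (is_intervals) x$start else x$time
  tz <- timezone %||%
    (if (length(tcol) > 0) attr(tcol, "tzone") else "UTC") %||% "UTC"
  m <- matrix(0, nrow = 1440, ncol = length(dates))
  for (j in seq_along(dates)) {
    midnight <- as.numeric(as.POSIXct(paste(dates[j], "00:00:00"), tz = tz))
    grid <- midnight + 60 * (0:1439)
    if (is_intervals && nrow(x) > 0) {
      for (i in seq_len(nrow(x))) {
        inside <- grid >= as.numeric(x$start[i]) & grid < as.numeric(x$end[i])
        m[inside, j] <- 1
      }
    } else if (is_activity && nrow(x) > 0) {
      idx <- match(grid, as.numeric(x$time))
      ok <- !is.na(idx)
      m[ok, j] <- x$activity[idx[ok]]
    }
  }
  m
}

hour_breaks <- function() {
  list(breaks = seq(0, 24, 6), labels = sprintf("%02d:00", seq(0, 24, 6)))
}

# Shared single-panel theming: clear labels and legends were a hard
# requirement from the review cycles.
habit_theme <- function() {
  ggplot2::theme_minimal(base_size = 11) +
    ggplot2::theme(legend.position = "bottom",
                   panel.grid.minor = ggplot2::element_blank())
}

#' Add clinical-event annotation markers to a plot
#'
#' Draws each annotation as a labelled vertical marker so clinical events
#' and interventions give context to the sensor data. Use `x_mode` to match
#' the plot's horizontal axis: timestamps for 24-hour views (`"datetime"`),
#' dates for multi-day views (`"date"`), or hours-of-day (`"hours"`, with
#' `ref_date` giving the civil date the axis starts on).
#'
#' @param p a ggplot.
#' @param annotations annotation tibble from [read_annotations()] (or `NULL`).
#' @param x_mode `"datetime"`, `"date"` or `"hours"`.
#' @param ref_date for `x_mode = "hours"`, the civil date at axis hour 0.
#' @return The plot with markers added.
#' @export
add_annotations <- function(p, annotations, x_mode = "date",
                            ref_date = NULL) {
  if (is.null(annotations) || nrow(annotations) == 0) return(p)
  ann <- as_tibble(annotations)
  xs <- switch(x_mode,
    datetime = ann$timestamp,
    date = as.Date(format(ann$timestamp, "%Y-%m-%d")),
    hours = {
      stopifnot(!is.null(ref_date))
      tz <- attr(ann$timestamp, "tzone") %||% "UTC"
      midnight <- as.POSIXct(paste(as.Date(ref_date), "00:00:00"), tz = tz)
      as.numeric(ann$timestamp - midnight, units = "hours")
    },
    abort("unknown x_mode"))
  ad <- tibble(x = xs, label = ann$label)
  p +
    ggplot2::geom_vline(data = ad,
                        ggplot2::aes(xintercept = .data$x),
                        linetype = "dashed", colour = "purple") +
    ggplot2::geom_text(data = ad,
                       ggplot2::aes(x = .data$x, y = Inf,
                                    label = .data$label),
                       vjust = 1.2, hjust = -0.05, size = 3,
                       colour = "purple")
}

#' 24-hour usage timeline (views 1.2 and 1.3)
#'
#' Shows the bed sensor's in-use spans for one 24-hour civil day as blue
#' blocks on a time-of-day axis (view 1.2, the simplest and best-liked
#' form). With a per-minute usual pattern supplied, the usage-state
#' probability is superimposed in a darker tint (view 1.3).
#'
#' @param intervals occupancy intervals (`start`, `end`).
#' @param date civil date to display.
#' @param pattern optional [usual_pattern()] over minute bins 0-1439.
#' @param config a [render_config()].
#' @return A ggplot.
#' @export
plot_usage_day <- function(intervals, date, pattern = NULL,
                           config = render_config()) {
  date <- as.Date(date)
  iv <- as_tibble(intervals)
  tz <- if (nrow(iv) > 0) attr(iv$start, "tzone") %||% "UTC" else "UTC"
  midnight <- as.POSIXct(paste(date, "00:00:00"), tz = tz)
  day_end <- as.POSIXct(paste(date + 1, "00:00:00"), tz = tz)
  iv <- dplyr::filter(iv, .data$end > midnight, .data$start < day_end)
  seg <- tibble(
    xmin = as.numeric(pmax(iv$start, midnight) - midnight, units = "hours"),
    xmax = as.numeric(pmin(iv$end, day_end) - midnight, units = "hours"))
  hb <- hour_breaks()
  p <- ggplot2::ggplot()
  if (!is.null(pattern)) {
    stopifnot(inherits(pattern, "usual_pattern"))
    pb <- tidy(pattern)
    p <- p + ggplot2::geom_area(
      data = tibble(x = pb$bin / 60, y = pb$mean),
      ggplot2::aes(x = .data$x, y = .data$y, fill = "usual pattern"),
      alpha = 0.9)
  }
  if (nrow(seg) > 0) {
    p <- p + ggplot2::geom_rect(
      data = seg,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = 0, ymax = 1, fill = "in use"),
      alpha = if (is.null(pattern)) 1 else 0.55)
  }
  p +
    ggplot2::scale_fill_manual(
      name = NULL,
      values = c("in use" = config$actual,
                 "usual pattern" = config$pattern),
      drop = FALSE) +
    ggplot2::scale_x_continuous(limits = c(0, 24), breaks = hb$breaks,
                                labels = hb$labels) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "time of day", y = NULL,
                  title = paste("Bed usage,", format(date))) +
    habit_theme()
}

#' 24-hour motion events per hour (views 2.4 and 2.5)
#'
#' `plot_motion_hourly()` draws the day's hourly motion-event counts as blue
#' bars with the usual pattern superimposed as a dark step line (view 2.4).
#' `plot_motion_difference()` draws only the signed per-hour difference from
#' the usual pattern (view 2.5) — the form reviewers found easiest to
#' assimilate.
#'
#' @param hourly tibble from [hourly_counts()].
#' @param pattern optional [usual_pattern()] over hour bins 0-23.
#' @param diff difference tibble from [difference_series()].
#' @param date display date (for the title).
#' @param config a [render_config()].
#' @return A ggplot.
#' @export
plot_motion_hourly <- function(hourly, pattern = NULL,
                               config = render_config()) {
  h <- as_tibble(hourly)
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$hour + 0.5,
                                       y = .data$count)) +
    ggplot2::geom_col(ggplot2::aes(fill = "actual"), width = 0.9)
  if (!is.null(pattern)) {
    stopifnot(inherits(pattern, "usual_pattern"))
    pb <- tidy(pattern)
    p <- p + ggplot2::geom_step(
      data = tibble(x = c(pb$bin, 24), y = c(pb$mean, pb$mean[24])),
      ggplot2::aes(x = .data$x, y = .data$y, colour = "usual pattern"),
      linewidth = 0.8)
  }
  hb <- hour_breaks()
  p +
    ggplot2::scale_fill_manual(name = NULL,
                               values = c("actual" = config$actual)) +
    ggplot2::scale_colour_manual(name = NULL,
                                 values = c("usual pattern" = config$pattern)) +
    ggplot2::scale_x_continuous(limits = c(0, 24), breaks = hb$breaks,
                                labels = hb$labels) +
    ggplot2::labs(x = "time of day", y = "motion events / hour",
                  title = paste("Motion events per hour,",
                                format(h$date[1]))) +
    habit_theme()
}

#' @rdname plot_motion_hourly
#' @export
plot_motion_difference <- function(diff, date = NULL,
                                   config = render_config()) {
  d <- as_tibble(diff)
  stopifnot(all(c("bin", "difference") %in% names(d)))
  hb <- hour_breaks()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin + 0.5,
                                  y = .data$difference)) +
    ggplot2::geom_col(ggplot2::aes(fill = "difference from usual"),
                      width = 0.9) +
    ggplot2::geom_hline(yintercept = 0, colour = config$pattern) +
    ggplot2::scale_fill_manual(name = NULL,
                               values = c("difference from usual" =
                                            config$actual)) +
    ggplot2::scale_x_continuous(limits = c(0, 24), breaks = hb$breaks,
                                labels = hb$labels) +
    ggplot2::labs(x = "time of day", y = "events / hour vs usual",
                  title = paste0("Motion difference from usual pattern",
                                 if (!is.null(date)) paste0(", ",
                                                            format(date)))) +
    habit_theme()
}

#' Daily feature series: actual points, running average as a solid line
#'
#' The final-cycle presentation for all multi-day series (views 3.1, 4.1,
#' 6.2, 7.1, 7.2): the actual daily values are drawn only as points and the
#' trailing running average as a solid line, with calendar dates on the
#' horizontal axis. `series` may hold several named features (one colour
#' each); per review feedback, prefer one feature per panel.
#'
#' @param series tibble with columns `date`, `value`, and optionally
#'   `feature` (names) and `smoothed` (precomputed running average).
#' @param window_days running-average window when `smoothed` is absent.
#' @param ylab,title axis label and title.
#' @param palette named colours per feature; defaults to the config colours.
#' @param config a [render_config()].
#' @return A ggplot.
#' @export
plot_daily_series <- function(series, window_days = 7, ylab = "value",
                              title = NULL, palette = NULL,
                              config = render_config()) {
  s <- as_tibble(series)
  if (!"feature" %in% names(s)) s$feature <- "value"
  if (!"smoothed" %in% names(s)) {
    s <- dplyr::group_by(s, .data$feature)
    s <- dplyr::group_modify(s, function(df, key) {
      tidy(running_average(df, window_days = window_days))
    })
    s <- dplyr::ungroup(s)
  }
  feats <- unique(s$feature)
  if (is.null(palette)) {
    defaults <- c(config$actual, config$in_bed, config$out_of_bed, "orange")
    palette <- stats::setNames(rep(defaults, length.out = length(feats)),
                               feats)
  }
  ggplot2::ggplot(s, ggplot2::aes(x = .data$date, colour = .data$feature)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), size = 1.4,
                        na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), linewidth = 0.8,
                       na.rm = TRUE) +
    ggplot2::scale_colour_manual(name = NULL, values = palette) +
    ggplot2::labs(x = "date", y = ylab, title = title) +
    habit_theme()
}

#' Stacked running-average in/out-of-bed hours (view 3.6)
#'
#' Stacked area graph of the running-average time in bed (green) and time
#' out of bed (red) per night. Deliberately contains no raw sensor points:
#' only the smoothed values are stacked, the form reviewers rated
#' 'best so far'.
#'
#' @param features nightly feature tibble from [nightly_feature_table()].
#' @param window_days running-average window, days.
#' @param config a [render_config()].
#' @return A ggplot.
#' @export
plot_usage_stacked_area <- function(features, window_days = 7,
                                    config = render_config()) {
  f <- as_tibble(features)
  ra <- function(v) running_average(
    tibble(date = f$anchor_date, value = v), window_days)$smoothed
  long <- dplyr::bind_rows(
    tibble(date = f$anchor_date, feature = "time out of bed",
           hours = ra(f$accumulated_period_out_of_bed / 3600)),
    tibble(date = f$anchor_date, feature = "time in bed",
           hours = ra(f$accumulated_period_in_bed / 3600)))
  long$feature <- factor(long$feature,
                         levels = c("time out of bed", "time in bed"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$date, y = .data$hours,
                                     fill = .data$feature)) +
    ggplot2::geom_area(position = "stack", na.rm = TRUE) +
    ggplot2::scale_fill_manual(
      name = NULL,
      values = c("time in bed" = config$in_bed,
                 "time out of bed" = config$out_of_bed)) +
    ggplot2::labs(x = "date", y = "hours (running average)",
                  title = "Nightly bed occupancy, stacked running averages") +
    habit_theme()
}

#' Raw day-strip view (view 5.1)
#'
#' Each 24-hour period drawn as a vertical strip, strips side by side for
#' the whole monitoring period: dates on the horizontal axis, time of day on
#' the vertical. For the usage sensor, in use is dark and not in use white;
#' shifts in the daily rhythm show up as drifting dark bands.
#'
#' @param x occupancy intervals or activity tibble (see
#'   [build_day_strip_matrix()]).
#' @param dates Date vector.
#' @param config a [render_config()].
#' @return A ggplot.
#' @export
plot_day_strips <- function(x, dates, config = render_config()) {
  dates <- as.Date(dates)
  m <- build_day_strip_matrix(x, dates)
  df <- tibble(
    date = rep(dates, each = 1440),
    minute = rep(0:1439, times = length(dates)),
    value = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$date,
                                   y = .data$minute / 60,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(name = "level", low = "white",
                                 high = "grey10") +
    ggplot2::scale_y_continuous(breaks = seq(0, 24, 6),
                                labels = sprintf("%02d:00", seq(0, 24, 6)),
                                expand = c(0, 0)) +
    ggplot2::labs(x = "date", y = "time of day",
                  title = "Raw sensor data by day") +
    habit_theme()
}

#' Nocturnal inactivity times (view 6.1)
#'
#' Start and end of nocturnal inactivity per night as clock times on an
#' 18:00-anchored axis, points plus running-average lines.
#'
#' @inheritParams plot_usage_stacked_area
#' @return A ggplot.
#' @export
plot_inactivity_times <- function(features, window_days = 7,
                                  config = render_config()) {
  f <- as_tibble(features)
  anchored <- function(t) {
    h <- as.numeric(t - as.POSIXct(paste(f$anchor_date, "18:00:00"),
                                   tz = attr(t, "tzone") %||% "UTC"),
                    units = "hours") + 18
    h
  }
  long <- dplyr::bind_rows(
    tibble(date = f$anchor_date, feature = "start of inactivity",
           value = anchored(f$start_of_inactivity)),
    tibble(date = f$anchor_date, feature = "end of inactivity",
           value = anchored(f$end_of_inactivity)))
  plot_daily_series(long, window_days = window_days,
                    ylab = "clock time (hours since midnight)",
                    title = "Nocturnal inactivity times",
                    palette = c("start of inactivity" = config$in_bed,
                                "end of inactivity" = config$out_of_bed),
                    config = config)
}

#' Render one catalogue view to an image file
#'
#' Thin file-writing wrapper over the `plot_*()` builders: checks the data
#' matches the view, builds the figure, overlays annotations and writes
#' `out`. Views are rendered from processed artifacts (features, baselines)
#' and never recompute them, so computation stays testable without image
#' comparison.
#'
#' @param view identifier from [implemented_views()].
#' @param data the view's processed inputs; see Details of each `plot_*()`
#'   function. A list whose elements are passed by name.
#' @param annotations optional annotation tibble.
#' @param config a [render_config()].
#' @param out output file path.
#' @return `out`, invisibly.
#' @export
render_view <- function(view, data, annotations = NULL,
                        config = render_config(), out) {
  if (!view %in% implemented_views()) {
    abort(paste0("unknown view id: ", view, " (implemented: ",
                 paste(implemented_views(), collapse = ", "), ")"))
  }
  p <- build_view(view, data, config)
  x_mode <- if (view %in% c("1.2", "1.3", "2.4", "2.5")) "hours" else "date"
  ref_date <- if (x_mode == "hours") data$date else NULL
  p <- add_annotations(p, annotations, x_mode = x_mode, ref_date = ref_date)
  ggplot2::ggsave(out, p, width = config$width, height = config$height,
                  dpi = config$dpi)
  invisible(out)
}

build_view <- function(view, data, config) {
  need <- function(...) {
    miss <- setdiff(c(...), names(data))
    if (length(miss) > 0) {
      abort(paste0("view ", view, " needs data element(s): ",
                   paste(miss, collapse = ", ")))
    }
  }
  switch(view,
    "1.2" = { need("intervals", "date")
      plot_usage_day(data$intervals, data$date, config = config) },
    "1.3" = { need("intervals", "date", "pattern")
      plot_usage_day(data$intervals, data$date, pattern = data$pattern,
                     config = config) },
    "2.4" = { need("hourly")
      plot_motion_hourly(data$hourly, pattern = data$pattern,
                         config = config) },
    "2.5" = { need("diff")
      plot_motion_difference(data$diff, date = data$date, config = config) },
    "3.1" = { need("features")
      f <- as_tibble(data$features)
      long <- dplyr::bind_rows(
        tibble(date = f$anchor_date, feature = "time in bed (h)",
               value = f$accumulated_period_in_bed / 3600),
        tibble(date = f$anchor_date, feature = "time out of bed (h)",
               value = f$accumulated_period_out_of_bed / 3600))
      plot_daily_series(long, window_days = data$window_days %||% 7,
                        ylab = "hours", title = "Nightly bed occupancy hours",
                        palette = c("time in bed (h)" = config$in_bed,
                                    "time out of bed (h)" =
                                      config$out_of_bed),
                        config = config) },
    "3.6" = { need("features")
      plot_usage_stacked_area(data$features,
                              window_days = data$window_days %||% 7,
                              config = config) },
    "4.1" = { need("series")
      plot_daily_series(data$series, window_days = data$window_days %||% 7,
                        ylab = "usage events / day",
                        title = "Daily usage-sensor events",
                        config = config) },
    "5.1" = { need("x", "dates")
      plot_day_strips(data$x, data$dates, config = config) },
    "6.1" = { need("features")
      plot_inactivity_times(data$features,
                            window_days = data$window_days %||% 7,
                            config = config) },
    "6.2" = { need("features")
      f <- as_tibble(data$features)
      plot_daily_series(
        tibble(date = f$anchor_date,
               value = f$duration_of_inactivity / 3600),
        window_days = data$window_days %||% 7, ylab = "hours",
        title = "Nocturnal inactivity duration", config = config) },
    "7.1" = { need("series")
      plot_daily_series(data$series, window_days = data$window_days %||% 7,
                        ylab = "motion events / day",
                        title = "Daily motion-sensor events",
                        config = config) },
    "7.2" = { need("series")
      plot_daily_series(data$series, window_days = data$window_days %||% 7,
                        ylab = "motion events",
                        title = "Daily motion events by day part",
                        config = config) }
  )
}

#' Render the full report for a stream
#'
#' Renders every implemented view applicable to the sensors present in the
#' stream, one feature per panel, into `out_dir`, with deterministic file
#' names `<subject>_<view>_<from>_<to>.<ext>` and a plain-text `index.md`
#' listing the files. Usage views are skipped (with a note) when the stream
#' has no usage sensor, and likewise for motion.
#'
#' @param events event-stream tibble.
#' @param dates Date vector of anchor dates to cover.
#' @param annotations optional annotation tibble.
#' @param config a [render_config()].
#' @param out_dir output directory (created if needed).
#' @param window_days running-average window for daily-series views.
#' @param pattern_window days in the usual-pattern window.
#' @return Tibble of rendered files (`view`, `path`), invisibly.
#' @export
render_report <- function(events, dates, annotations = NULL,
                          config = render_config(), out_dir,
                          window_days = 7, pattern_window = 21) {
  ev <- validate_event_stream(events)
  dates <- as.Date(dates)
  if (length(dates) == 0 || nrow(ev) == 0) abort("no data in range")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  subject <- ev$subject_id[1]
  tz <- attr(ev$timestamp, "tzone") %||% "UTC"
  has_usage <- any(ev$sensor_type == "usage")
  has_motion <- any(ev$sensor_type == "motion")
  stamp <- paste0(format(min(dates)), "_", format(max(dates)))
  ext <- config$format
  fname <- function(view) file.path(
    out_dir, paste0(subject, "_", view, "_", stamp, ".", ext))
  last_date <- max(dates)
  feats <- nightly_feature_table(ev, dates)
  out <- list()
  emit <- function(view, data) {
    path <- fname(view)
    render_view(view, data, annotations = annotations, config = config,
                out = path)
    out[[length(out) + 1L]] <<- tibble(view = view, path = path)
  }
  if (has_usage) {
    intervals <- suppressWarnings(pair_occupancy(ev))
    emit("1.2", list(intervals = intervals, date = last_date))
    mp <- usual_pattern(daily_usage_minute_profiles(intervals, dates),
                        as_of = last_date, window_days = pattern_window)
    if (mp$available) {
      emit("1.3", list(intervals = intervals, date = last_date,
                       pattern = mp))
    } else {
      inform("skipping view 1.3: usual pattern unavailable")
    }
    emit("3.1", list(features = feats, window_days = window_days))
    emit("3.6", list(features = feats, window_days = window_days))
    usage_daily <- purrr::map_dfr(dates, function(d) {
      w <- night_window(d, timezone = tz)
      tibble(date = d,
             value = sum(ev$sensor_type == "usage" &
                           ev$timestamp >= w$start & ev$timestamp <= w$end))
    })
    emit("4.1", list(series = usage_daily, window_days = window_days))
    emit("5.1", list(x = intervals, dates = dates))
  } else {
    inform("no usage sensor in stream; skipping usage views")
  }
  if (has_motion) {
    hp <- usual_pattern(daily_hourly_profiles(ev, dates),
                        as_of = last_date, window_days = pattern_window)
    hc <- hourly_counts(ev, last_date)
    emit("2.4", list(hourly = hc,
                     pattern = if (hp$available) hp else NULL))
    if (hp$available) {
      d <- difference_series(
        tibble(bin = hc$hour, value = as.numeric(hc$count)), hp)
      emit("2.5", list(diff = d, date = last_date))
    } else {
      inform("skipping view 2.5: usual pattern unavailable")
    }
    emit("6.1", list(features = feats, window_days = window_days))
    emit("6.2", list(features = feats, window_days = window_days))
    motion_daily <- purrr::map_dfr(dates, function(d) {
      dp <- day_part_counts(ev, d)
      tibble(date = d, value = as.numeric(
        dp$morning_count + dp$daytime_count + dp$nighttime_count))
    })
    emit("7.1", list(series = motion_daily, window_days = window_days))
    dp_long <- purrr::map_dfr(dates, function(d) {
      dp <- day_part_counts(ev, d)
      tibble(date = d,
             feature = c("morning", "daytime", "nighttime"),
             value = as.numeric(c(dp$morning_count, dp$daytime_count,
                                  dp$nighttime_count)))
    })
    emit("7.2", list(series = dp_long, window_days = window_days))
  } else {
    inform("no motion sensor in stream; skipping motion views")
  }
  res <- dplyr::bind_rows(out)
  idx <- c(paste0("# Habits report: ", subject, " (", stamp, ")"), "",
           paste0("- [", res$view, "](", basename(res$path), ")"))
  writeLines(idx, file.path(out_dir, "index.md"))
  invisible(res)
}

#' Autoplot methods for baseline objects
#'
#' `autoplot()` on a [usual_pattern()] draws the per-bin mean with a
#' mean +/- k sd ribbon; on a [running_average()] it draws the standard
#' points-plus-trend presentation.
#'
#' @param object a `usual_pattern` or `running_average`.
#' @param k ribbon half-width in standard deviations.
#' @param config a [render_config()].
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.usual_pattern <- function(object, k = 1, config = render_config(),
                                   ...) {
  if (!object$available) {
    abort("usual pattern unavailable (insufficient history)")
  }
  b <- deviation_bounds(object, k = k)
  if (!is.numeric(b$bin)) b$bin <- seq_along(b$bin)
  ggplot2::ggplot(b, ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = config$pattern, alpha = 0.2, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean),
                       colour = config$pattern, linewidth = 0.8) +
    ggplot2::labs(x = "bin", y = "usual level",
                  title = paste0("Usual pattern (", 
                                 length(object$contributing_dates),
                                 " days)")) +
    habit_theme()
}

#' @rdname autoplot.usual_pattern
#' @exportS3Method ggplot2::autoplot
autoplot.running_average <- function(object, config = render_config(), ...) {
  plot_daily_series(tidy(object), ylab = "value",
                    title = paste0("Running average (",
                                   attr(object, "window_days"),
                                   "-day window)"),
                    config = config)
}
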