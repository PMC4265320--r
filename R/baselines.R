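#' Usual-pattern baseline
#'
#' The "usual pattern" is the per-bin average (and sample standard
#' deviation) of a subject's daily profiles over a trailing window, default
#' 21 days, ending strictly before the day under review: the template
#' describes "usual", not "today", so the displayed day never dilutes its own
#' anomaly. Works on any bin structure — 24 hourly counts, 3 day-part
#' counts, or 1440 per-minute usage-state indicators — as long as every
#' contributing day has the same bins.
#'
#' Distinct from [running_average()]: a usual pattern is a within-day shape
#' (one mean per bin, across days), a running average smooths a single
#' per-day series across days. Clinicians use the terms interchangeably; the
#' package keeps them as two named concepts.
#'
#' @param daily_profiles tibble with columns `date`, `bin`, `value`: one
#'   binned profile per date.
#' @param as_of the day under review; only dates strictly before it, within
#'   the trailing `window_days`, contribute.
#' @param window_days trailing window length, days.
#' @param min_days minimum number of complete contributing days; with fewer,
#'   the pattern is flagged unavailable and consumers render without the
#'   overlay.
#' @return A `usual_pattern` object: per-bin `mean` and `sd` plus metadata.
#'   `tidy()` returns the per-bin tibble, `glance()` a one-row summary.
#' @examples
#' prof <- tidyr::expand_grid(date = as.Date("2023-03-01") + 0:20, bin = 0:23)
#' prof$value <- 5
#' up <- usual_pattern(prof, as_of = as.Date("2023-03-22"))
#' glance(up)
#' @export
usual_pattern <- function(daily_profiles, as_of, window_days = 21,
                          min_days = 7) {
  stopifnot(window_days >= 1, min_days >= 1)
  dp <- as_tibble(daily_profiles)
  miss <- setdiff(c("date", "bin", "value"), names(dp))
  if (length(miss) > 0) {
    abort(paste0("daily_profiles missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  as_of <- as.Date(as_of)
  dp$date <- as.Date(dp$date)
  in_window <- dp$date >= as_of - window_days & dp$date < as_of
  dp <- dp[in_window & !is.na(dp$value), ]
  all_bins <- sort(unique(dp$bin))
  # complete days only: every bin present
  per_day <- dplyr::summarise(dplyr::group_by(dp, .data$date),
                              n_bins = dplyr::n_distinct(.data$bin))
  complete <- per_day$date[per_day$n_bins == length(all_bins)]
  dp <- dp[dp$date %in% complete, ]
  available <- length(complete) >= min_days && length(all_bins) > 0
  bins <- if (available) {
    dplyr::summarise(dplyr::group_by(dp, bin = .data$bin),
                     mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) sd(.data$value) else NA_real_,
                     .groups = "drop")
  } else {
    tibble(bin = all_bins, mean = NA_real_, sd = NA_real_)
  }
  structure(
    list(bins = bins, available = available, as_of = as_of,
         window_days = window_days, min_days = min_days,
         contributing_dates = sort(complete)),
    class = "usual_pattern")
}

#' @export
print.usual_pattern <- function(x, ...) {
  cat("<usual_pattern>", if (x$available) "" else "(unavailable)", "\n")
  cat("  as of", format(x$as_of), "- window", x$window_days, "days,",
      length(x$contributing_dates), "contributing days\n")
  if (x$available) print(x$bins, n = 5)
  invisible(x)
}

#' @rdname usual_pattern
#' @param x a `usual_pattern` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.usual_pattern <- function(x, ...) x$bins

#' @rdname usual_pattern
#' @exportS3Method generics::glance
glance.usual_pattern <- function(x, ...) {
  tibble(available = x$available, n_days = length(x$contributing_dates),
         window_days = x$window_days, as_of = x$as_of,
         n_bins = nrow(x$bins))
}

#' Trailing running average of a daily series
#'
#' Smooths a per-day feature series with a trailing mean over
#' `window_days` days ending at each date. Missing values are excluded from
#' both numerator and denominator; a date whose whole window is missing gets
#' a missing smoothed value. Trailing (not centred) because the tool is
#' prospective: at review time future data does not exist. The window length
#' is a first-class parameter — reviewers asked to be able to change it.
#'
#' @param series tibble with columns `date` and `value` (may contain `NA`).
#' @param window_days trailing window length, days (>= 1).
#' @return A `running_average` tibble: `date`, `value`, `smoothed`, with the
#'   window recorded as an attribute. `tidy()`/`glance()` methods available.
#' @examples
#' s <- tibble::tibble(date = as.Date("2023-03-01") + 0:3, value = 1:4)
#' running_average(s, window_days = 2)$smoothed # 1, 1.5, 2.5, 3.5
#' @export
running_average <- function(series, window_days = 7) {
  stopifnot(window_days >= 1)
  s <- as_tibble(series)
  miss <- setdiff(c("date", "value"), names(s))
  if (length(miss) > 0) {
    abort(paste0("series missing columns: ", paste(miss, collapse = ", ")))
  }
  s$date <- as.Date(s$date)
  s <- dplyr::arrange(s, .data$date)
  smoothed <- vapply(seq_len(nrow(s)), function(i) {
    in_win <- s$date > s$date[i] - window_days & s$date <= s$date[i]
    v <- s$value[in_win]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  out <- dplyr::mutate(s, smoothed = smoothed)
  attr(out, "window_days") <- window_days
  class(out) <- c("running_average", class(out))
  out
}

#' @rdname running_average
#' @param x a `running_average` tibble.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.running_average <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "running_average")
  out
}

#' @rdname running_average
#' @exportS3Method generics::glance
glance.running_average <- function(x, ...) {
  tibble(window_days = attr(x, "window_days"), n = nrow(x),
         n_missing = sum(is.na(x$value)))
}

#' Signed difference between a day's profile and the usual pattern
#'
#' Per-bin `actual - mean`; positive values mean more activity than usual.
#' Showing only the difference was the preferred final form of the hourly
#' motion view — easier and faster to assimilate than actual-plus-template.
#'
#' @param actual tibble with columns `bin`, `value` for the day under review.
#' @param pattern a [usual_pattern()] with the same bin structure.
#' @return Tibble `bin`, `actual`, `usual`, `difference`.
#' @export
difference_series <- function(actual, pattern) {
  stopifnot(inherits(pattern, "usual_pattern"))
  if (!pattern$available) {
    abort("usual pattern unavailable (insufficient history); cannot compute differences")
  }
  a <- as_tibble(actual)
  miss <- setdiff(c("bin", "value"), names(a))
  if (length(miss) > 0) {
    abort(paste0("actual missing columns: ", paste(miss, collapse = ", ")))
  }
  if (!identical(sort(a$bin), sort(pattern$bins$bin))) {
    abort("bin structures of actual and pattern do not match")
  }
  out <- dplyr::left_join(a, pattern$bins, by = "bin")
  dplyr::arrange(
    tibble(bin = out$bin, actual = out$value, usual = out$mean,
           difference = out$value - out$mean),
    .data$bin)
}

#' Deviation bounds around the usual pattern
#'
#' Per-bin `mean +/- k * sd` threshold lines drawn around the usual pattern.
#' Where the sd is undefined (a single contributing day) the bounds are
#' suppressed (`NA`).
#'
#' @param pattern a [usual_pattern()].
#' @param k half-width multiplier (default 1 sd).
#' @return Tibble `bin`, `mean`, `lower`, `upper`.
#' @export
deviation_bounds <- function(pattern, k = 1) {
  stopifnot(inherits(pattern, "usual_pattern"))
  if (!pattern$available) {
    abort("usual pattern unavailable (insufficient history)")
  }
  tibble(bin = pattern$bins$bin, mean = pattern$bins$mean,
         lower = pattern$bins$mean - k * pattern$bins$sd,
         upper = pattern$bins$mean + k * pattern$bins$sd)
}

#' Daily binned profiles from an event stream
#'
#' Builders for the profile shapes [usual_pattern()] consumes:
#' `daily_hourly_profiles()` gives 24 hourly motion-event counts per date;
#' `daily_day_part_profiles()` the three day-part counts per anchor date;
#' `daily_usage_minute_profiles()` a 1440-bin binary bed-occupancy state per
#' date (minute m is 1 when its starting instant lies inside an occupancy
#' interval).
#'
#' @param events event-stream tibble.
#' @param dates Date vector of (anchor) dates.
#' @param windows a [day_part_windows()] (day-part builder only).
#' @param intervals occupancy intervals (`start`, `end`) for the minute
#'   builder.
#' @return Tibble with columns `date`, `bin`, `value`.
#' @export
daily_hourly_profiles <- function(events, dates) {
  purrr::map_dfr(as.Date(dates), function(d) {
    h <- hourly_counts(events, d)
    tibble(date = d, bin = h$hour, value = as.numeric(h$count))
  })
}

#' @rdname daily_hourly_profiles
#' @export
daily_day_part_profiles <- function(events, dates,
                                    windows = day_part_windows()) {
  purrr::map_dfr(as.Date(dates), function(d) {
    p <- day_part_counts(events, d, windows)
    tibble(date = d, bin = c("morning", "daytime", "nighttime"),
           value = as.numeric(c(p$morning_count, p$daytime_count,
                                p$nighttime_count)))
  })
}

#' @rdname daily_hourly_profiles
#' @export
daily_usage_minute_profiles <- function(intervals, dates) {
  m <- build_day_strip_matrix(intervals, dates)
  purrr::map_dfr(seq_along(dates), function(j) {
    tibble(date = as.Date(dates)[j], bin = 0:1439, value = m[, j])
  })
}
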