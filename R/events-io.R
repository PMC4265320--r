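#' Event streams
#'
#' An event stream is a tibble with one row per discrete sensor event and
#' columns `timestamp` (POSIXct, second resolution, in the stream's civil
#' timezone), `subject_id`, `sensor_id`, `sensor_type` (`"motion"` or
#' `"usage"`) and `event_kind` (`"motion"`, `"usage_start"` or `"usage_end"`).
#' Motion sensors emit `motion` events; usage (pressure-pad) sensors emit
#' paired `usage_start`/`usage_end` messages. All downstream computation is
#' done in the stream's local civil time, because the analysis windows
#' (18:00 night anchor, the 06:00/10:00/22:00 day parts) are clock-of-day
#' concepts.
#'
#' @param timestamp POSIXct vector (with timezone).
#' @param subject_id,sensor_id character scalars or vectors.
#' @param sensor_type,event_kind character vectors; see Details.
#' @return A sorted, validated event-stream tibble.
#' @examples
#' es <- event_stream(
#'   timestamp = as.POSIXct("2023-03-01 22:00:00", tz = "Europe/London"),
#'   subject_id = "s1", sensor_id = "bed1",
#'   sensor_type = "usage", event_kind = "usage_start"
#' )
#' @export
event_stream <- function(timestamp, subject_id, sensor_id, sensor_type,
                         event_kind) {
  ev <- tibble(
    timestamp = timestamp,
    subject_id = as.character(subject_id),
    sensor_id = as.character(sensor_id),
    sensor_type = as.character(sensor_type),
    event_kind = as.character(event_kind)
  )
  validate_event_stream(ev)
}

.sensor_types <- c("motion", "usage")
.event_kinds <- c("motion", "usage_start", "usage_end")

#' Validate and sort an event-stream tibble
#'
#' Checks column presence/types, the sensor-type/event-kind pairing rules,
#' and returns the stream sorted by (timestamp, sensor_id, event_kind).
#'
#' @param events data frame of events.
#' @return The validated, sorted tibble.
#' @export
validate_event_stream <- function(events) {
  ev <- as_tibble(events)
  req <- c("timestamp", "subject_id", "sensor_id", "sensor_type", "event_kind")
  miss <- setdiff(req, names(ev))
  if (length(miss) > 0) {
    abort(paste0("event stream is missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  if (!inherits(ev$timestamp, "POSIXct")) {
    abort("`timestamp` must be POSIXct")
  }
  bad_type <- !ev$sensor_type %in% .sensor_types
  if (any(bad_type)) {
    abort(paste0("unknown sensor_type in rows: ",
                 paste(head(which(bad_type), 5), collapse = ", ")))
  }
  bad_kind <- !ev$event_kind %in% .event_kinds
  if (any(bad_kind)) {
    abort(paste0("unknown event_kind in rows: ",
                 paste(head(which(bad_kind), 5), collapse = ", ")))
  }
  # motion events come from motion sensors, usage_* from usage sensors
  mismatch <- (ev$event_kind == "motion") != (ev$sensor_type == "motion")
  if (any(mismatch)) {
    abort(paste0("sensor_type/event_kind mismatch in rows: ",
                 paste(head(which(mismatch), 5), collapse = ", ")))
  }
  dplyr::arrange(ev, .data$timestamp, .data$sensor_id, .data$event_kind)
}

# Parse ISO 8601 timestamps with numeric UTC offset ("+01:00" or "+0100"),
# returning POSIXct in `timezone`.
parse_iso8601 <- function(x, timezone) {
  x <- trimws(x)
  ok_shape <- grepl(
    "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}(Z|[+-]\\d{2}:?\\d{2})$", x)
  norm <- sub("Z$", "+0000", x)
  norm <- sub("([+-]\\d{2}):(\\d{2})$", "\\1\\2", norm)
  parsed <- as.POSIXct(norm, format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  parsed[!ok_shape] <- NA
  attr(parsed, "tzone") <- timezone
  parsed
}

format_iso8601 <- function(x) {
  out <- format(x, format = "%Y-%m-%dT%H:%M:%S%z")
  sub("([+-]\\d{2})(\\d{2})$", "\\1:\\2", out)
}

#' Read an event CSV file
#'
#' Reads the event CSV dialect: header
#' `timestamp,subject_id,sensor_id,sensor_type,event_kind`, one event per row,
#' timestamps in ISO 8601 with explicit UTC offset (e.g.
#' `2013-10-02T22:14:03+01:00`), which keeps the file unambiguous across
#' daylight-saving transitions. Rows are converted to the requested civil
#' timezone, duplicate identical rows are collapsed (telehealth links
#' retransmit), and the result is sorted.
#'
#' @param path path to the CSV file.
#' @param timezone IANA timezone name the stream should be expressed in.
#' @return An event-stream tibble (see [event_stream()]).
#' @export
read_events <- function(path, timezone = "Europe/London") {
  if (!file.exists(path)) {
    abort(paste0("event file not found: ", path))
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character())
  )
  req <- c("timestamp", "subject_id", "sensor_id", "sensor_type", "event_kind")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0) {
    abort(paste0("event CSV is missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    return(tibble(
      timestamp = as.POSIXct(character(), tz = timezone),
      subject_id = character(), sensor_id = character(),
      sensor_type = character(), event_kind = character()
    ))
  }
  ts <- parse_iso8601(raw$timestamp, timezone)
  if (anyNA(ts)) {
    abort(paste0("unparseable timestamp at data row(s): ",
                 paste(head(which(is.na(ts)), 5), collapse = ", ")))
  }
  bad_kind <- !raw$event_kind %in% .event_kinds
  if (any(bad_kind)) {
    abort(paste0(
      "unknown event_kind ", dQuote(raw$event_kind[which(bad_kind)[1]]),
      " at data row(s): ",
      paste(head(which(bad_kind), 5), collapse = ", ")))
  }
  bad_type <- !raw$sensor_type %in% .sensor_types
  if (any(bad_type)) {
    abort(paste0(
      "unknown sensor_type ", dQuote(raw$sensor_type[which(bad_type)[1]]),
      " at data row(s): ",
      paste(head(which(bad_type), 5), collapse = ", ")))
  }
  ev <- tibble(
    timestamp = ts,
    subject_id = raw$subject_id,
    sensor_id = raw$sensor_id,
    sensor_type = raw$sensor_type,
    event_kind = raw$event_kind
  )
  ev <- dplyr::distinct(ev)
  validate_event_stream(ev)
}

#' Write an event stream to CSV
#'
#' Inverse of [read_events()]: `read_events(write_events(s, f))` reproduces
#' `s` exactly (timestamps re-expressed in the same zone never shift).
#'
#' @param events event-stream tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  ev <- validate_event_stream(events)
  out <- dplyr::mutate(ev, timestamp = format_iso8601(.data$timestamp))
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a clinical-event annotation CSV
#'
#' Annotations mark clinical events or interventions so they can be overlaid
#' on visualizations for context. Dialect: header `timestamp,category,label`,
#' ISO 8601 timestamps, `category` one of `clinical_event`, `intervention`,
#' `other`.
#'
#' @inheritParams read_events
#' @return Tibble with columns `timestamp`, `category`, `label`.
#' @export
read_annotations <- function(path, timezone = "Europe/London") {
  if (!file.exists(path)) {
    abort(paste0("annotation file not found: ", path))
  }
  raw <- readr::read_csv(
    path, col_types = readr::cols(.default = readr::col_character()))
  miss <- setdiff(c("timestamp", "category", "label"), names(raw))
  if (length(miss) > 0) {
    abort(paste0("annotation CSV is missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    return(tibble(timestamp = as.POSIXct(character(), tz = timezone),
                  category = character(), label = character()))
  }
  ts <- parse_iso8601(raw$timestamp, timezone)
  if (anyNA(ts)) {
    abort(paste0("unparseable annotation timestamp at row(s): ",
                 paste(head(which(is.na(ts)), 5), collapse = ", ")))
  }
  bad <- !raw$category %in% c("clinical_event", "intervention", "other")
  if (any(bad)) {
    abort(paste0("unknown annotation category at row(s): ",
                 paste(head(which(bad), 5), collapse = ", ")))
  }
  if (any(!nzchar(trimws(raw$label)))) {
    abort("annotation labels must be non-empty")
  }
  dplyr::arrange(
    tibble(timestamp = ts, category = raw$category, label = raw$label),
    .data$timestamp)
}

#' Pair usage start/end events into occupancy intervals
#'
#' Walks each usage sensor's `usage_start`/`usage_end` messages in time order
#' and pairs them into occupancy intervals. Real deployments lose messages,
#' so irregularities degrade gracefully rather than fail:
#' \itemize{
#'   \item a leading `usage_end` with no open interval is dropped;
#'   \item a `usage_start` while an interval is already open is ignored
#'     (the first start wins);
#'   \item a trailing unmatched `usage_start` is closed at the last event
#'     time in the stream and flagged `censored`.
#' }
#' Each irregularity raises a warning and is counted in the `diagnostics`
#' attribute of the result (`unmatched_end_dropped`, `duplicate_start_ignored`,
#' `censored_open_interval`, `n_intervals`).
#'
#' @param events event-stream tibble containing usage events.
#' @return Tibble with columns `sensor_id`, `start`, `end`, `censored`
#'   (logical), sorted and non-overlapping within each sensor; diagnostics in
#'   `attr(, "diagnostics")`.
#' @examples
#' es <- event_stream(
#'   timestamp = as.POSIXct(c("2023-03-01 22:00:00", "2023-03-02 06:30:00"),
#'                          tz = "Europe/London"),
#'   subject_id = "s1", sensor_id = "bed1", sensor_type = "usage",
#'   event_kind = c("usage_start", "usage_end")
#' )
#' pair_occupancy(es)
#' @export
pair_occupancy <- function(events) {
  ev <- validate_event_stream(events)
  usage <- dplyr::filter(ev, .data$sensor_type == "usage")
  diag <- list(unmatched_end_dropped = 0L, duplicate_start_ignored = 0L,
               censored_open_interval = 0L, n_intervals = 0L)
  tz <- attr(ev$timestamp, "tzone") %||% "UTC"
  empty <- tibble(sensor_id = character(),
                  start = as.POSIXct(character(), tz = tz),
                  end = as.POSIXct(character(), tz = tz),
                  censored = logical())
  if (nrow(usage) == 0) {
    diag$n_intervals <- 0L
    attr(empty, "diagnostics") <- diag
    return(empty)
  }
  stream_end <- max(ev$timestamp)
  out <- list()
  for (sid in unique(usage$sensor_id)) {
    se <- dplyr::filter(usage, .data$sensor_id == sid)
    open <- NULL
    for (i in seq_len(nrow(se))) {
      kind <- se$event_kind[i]
      t <- se$timestamp[i]
      if (kind == "usage_start") {
        if (is.null(open)) {
          open <- t
        } else {
          diag$duplicate_start_ignored <- diag$duplicate_start_ignored + 1L
          warn(paste0("usage_start at ", format(t), " on sensor ", sid,
                      " while interval already open; ignored"))
        }
      } else { # usage_end
        if (is.null(open)) {
          diag$unmatched_end_dropped <- diag$unmatched_end_dropped + 1L
          warn(paste0("unmatched usage_end at ", format(t), " on sensor ",
                      sid, "; dropped"))
        } else if (t > open) {
          out[[length(out) + 1L]] <-
            tibble(sensor_id = sid, start = open, end = t, censored = FALSE)
          open <- NULL
        } else {
          # zero-length state: drop both silently-with-warning
          diag$unmatched_end_dropped <- diag$unmatched_end_dropped + 1L
          warn(paste0("usage_end at ", format(t), " not after its start; ",
                      "pair dropped"))
          open <- NULL
        }
      }
    }
    if (!is.null(open)) {
      diag$censored_open_interval <- diag$censored_open_interval + 1L
      warn(paste0("open interval on sensor ", sid,
                  " censored at stream end ", format(stream_end)))
      if (stream_end > open) {
        out[[length(out) + 1L]] <-
          tibble(sensor_id = sid, start = open, end = stream_end,
                 censored = TRUE)
      }
    }
  }
  res <- if (length(out) > 0) {
    dplyr::arrange(dplyr::bind_rows(out), .data$sensor_id, .data$start)
  } else {
    empty
  }
  diag$n_intervals <- nrow(res)
  attr(res, "diagnostics") <- diag
  res
}
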