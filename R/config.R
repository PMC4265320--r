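#' Pipeline configuration
#'
#' A single human-editable tree of every tunable parameter in the pipeline.
#' The defaults are the deployed-system values: Gaussian sigma 15 minutes
#' truncated at 3 sigma, day parts 06:00/10:00/22:00, night window
#' 18:00-12:00, 21-day usual-pattern window, 2-minute motion dead time,
#' 30-second usage minimum registration.
#'
#' @param ... overrides as nested named lists matching the default
#'   structure, e.g. `kernel = list(sigma = 10)`. Unknown keys are rejected.
#' @return A validated `pipeline_config` list.
#' @examples
#' cfg <- pipeline_config(usual_pattern = list(window_days = 14))
#' cfg$usual_pattern$window_days
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    timezone = "Europe/London",
    kernel = list(sigma = 15, truncation_multiple = 3, resolution = 1),
    day_parts = list(morning_start = "06:00", daytime_start = "10:00",
                     nighttime_start = "22:00"),
    night_window = list(start = "18:00", end = "12:00"),
    features = list(min_gap = 10800),
    usual_pattern = list(window_days = 21, min_days = 7),
    running_average = list(window_days = 7),
    deviation = list(k = 1),
    physics = list(motion_dead_time = 120, usage_min_registration = 30),
    render = list(format = "png", actual = "#1f77b4", pattern = "grey25",
                  in_bed = "forestgreen", out_of_bed = "firebrick",
                  width = 8, height = 4.5, dpi = 120)
  )
  overrides <- list(...)
  cfg <- merge_config(defaults, overrides, path = character())
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

merge_config <- function(base, overrides, path) {
  if (length(overrides) == 0) return(base)
  nms <- names(overrides)
  if (is.null(nms) || any(!nzchar(nms))) {
    abort(paste0("config overrides must be named (at ",
                 paste(path, collapse = "."), ")"))
  }
  for (k in nms) {
    key_path <- paste(c(path, k), collapse = ".")
    if (!k %in% names(base)) {
      abort(paste0("unknown config key: ", key_path))
    }
    if (is.list(base[[k]])) {
      if (!is.list(overrides[[k]])) {
        abort(paste0("config key ", key_path, " must be a list"))
      }
      base[[k]] <- merge_config(base[[k]], overrides[[k]],
                                c(path, k))
    } else {
      base[[k]] <- overrides[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  chk <- function(ok, key, msg) {
    if (!ok) abort(paste0("invalid config value at ", key, ": ", msg))
  }
  chk(is.numeric(cfg$kernel$sigma) && cfg$kernel$sigma > 0,
      "kernel.sigma", "must be a positive number of minutes")
  chk(cfg$kernel$truncation_multiple > 0, "kernel.truncation_multiple",
      "must be positive")
  chk(cfg$kernel$resolution > 0 &&
        cfg$kernel$resolution <= cfg$kernel$sigma,
      "kernel.resolution", "must be positive and not exceed sigma")
  chk(cfg$features$min_gap > 0, "features.min_gap",
      "must be positive seconds")
  chk(cfg$usual_pattern$window_days >= 1, "usual_pattern.window_days",
      "must be >= 1")
  chk(cfg$usual_pattern$min_days >= 1, "usual_pattern.min_days",
      "must be >= 1")
  chk(cfg$running_average$window_days >= 1, "running_average.window_days",
      "must be >= 1")
  chk(cfg$physics$motion_dead_time > 0, "physics.motion_dead_time",
      "must be positive seconds")
  chk(cfg$physics$usage_min_registration > 0,
      "physics.usage_min_registration", "must be positive seconds")
  chk(cfg$deviation$k >= 0, "deviation.k", "must be non-negative")
  # constructs that validate themselves
  do.call(day_part_windows, cfg$day_parts)
  parse_clock_hours(cfg$night_window$start)
  parse_clock_hours(cfg$night_window$end)
  invisible(cfg)
}

#' Load a pipeline configuration from a YAML file
#'
#' With no file, returns the defaults. File keys override defaults; unknown
#' keys and invalid values are rejected with the offending key path in the
#' message.
#'
#' @param path optional YAML file.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(pipeline_config())
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  overrides <- yaml::read_yaml(path)
  if (is.null(overrides)) return(pipeline_config())
  do.call(pipeline_config, overrides)
}

#' Write a configuration to YAML
#'
#' @param config a `pipeline_config`.
#' @param path output file; when `NULL` the YAML text is returned.
#' @export
dump_config <- function(config = pipeline_config(), path = NULL) {
  txt <- yaml::as.yaml(unclass(config))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
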