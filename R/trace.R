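#' Sensor taxonomy
#'
#' The home device carries two classes of sensors: periodic channels sampled
#' once per minute (temperature in degrees Celsius, relative humidity in %,
#' barometric pressure in hPa, light level in % of full brightness, and a
#' unitless combustible-gas level) and binary event channels that produce a
#' record only when triggered (motion, fire, gas presence, TV-remote infrared
#' and shock).
#'
#' @return Character vector of sensor names.
#' @export
periodic_sensors <- function() {
  c("temperature", "humidity", "pressure", "light", "gas_level")
}

#' @rdname periodic_sensors
#' @export
event_sensors <- function() {
  c("motion", "fire", "gas_presence", "tv_remote", "shock")
}

#' @rdname periodic_sensors
#' @export
sensor_kinds <- function() c(periodic_sensors(), event_sensors())

# plausibility bounds used by validate_trace() and trace ingestion
.sensor_bounds <- list(
  temperature = c(-20, 60),
  humidity = c(0, 100),
  pressure = c(850, 1100),
  light = c(0, 100),
  gas_level = c(0, Inf)
)

#' Construct a one-day sensor trace
#'
#' A `daily_trace` bundles everything one calendar day produced: periodic
#' readings (one row per sensor per minute) and triggered events. Readings
#' are sorted by minute within sensor; events are sorted by minute (ties are
#' allowed, e.g. repeated gas detections within a minute are distinct
#' records). The constructor validates column types and sensor names but
#' deliberately does not enforce cadence or value bounds -- that is the job
#' of [validate_trace()], so that malformed traces can be represented and
#' diagnosed.
#'
#' @param date A `Date` (single day).
#' @param readings Tibble/data frame with columns `minute` (integer, 0-1439),
#'   `sensor` (periodic sensor name) and `value` (numeric).
#' @param events Tibble/data frame with columns `minute` and `sensor` (event
#'   sensor name). May be empty.
#' @return An object of class `daily_trace`.
#' @examples
#' daily_trace(as.Date("2021-03-03"),
#'             readings = tibble::tibble(minute = 0:2, sensor = "temperature",
#'                                       value = c(20, 20.1, 20)),
#'             events = tibble::tibble(minute = 610L, sensor = "motion"))
#' @export
daily_trace <- function(date, readings = NULL, events = NULL) {
  if (!inherits(date, "Date") || length(date) != 1L || is.na(date)) {
    stop("`date` must be a single Date")
  }
  if (is.null(readings)) {
    readings <- tibble::tibble(minute = integer(0), sensor = character(0),
                               value = numeric(0))
  }
  if (is.null(events)) {
    events <- tibble::tibble(minute = integer(0), sensor = character(0))
  }
  readings <- tibble::as_tibble(readings)[, c("minute", "sensor", "value")]
  events <- tibble::as_tibble(events)[, c("minute", "sensor")]
  readings$minute <- as.integer(readings$minute)
  events$minute <- as.integer(events$minute)
  readings$value <- as.numeric(readings$value)
  if (nrow(readings) && (any(readings$minute < 0L) || any(readings$minute > 1439L))) {
    stop("reading minutes must lie in [0, 1440)")
  }
  if (nrow(events) && (any(events$minute < 0L) || any(events$minute > 1439L))) {
    stop("event minutes must lie in [0, 1440)")
  }
  bad_p <- setdiff(unique(readings$sensor), periodic_sensors())
  if (length(bad_p)) stop("unknown periodic sensor: ", paste(bad_p, collapse = ", "))
  bad_e <- setdiff(unique(events$sensor), event_sensors())
  if (length(bad_e)) stop("unknown event sensor: ", paste(bad_e, collapse = ", "))
  readings <- readings[order(readings$sensor, readings$minute), ]
  events <- events[order(events$minute, events$sensor), ]
  structure(list(date = date, readings = readings, events = events),
            class = "daily_trace")
}

#' @export
print.daily_trace <- function(x, ...) {
  cat(sprintf("<daily_trace> %s: %d readings (%s), %d events (%s)\n",
              format(x$date), nrow(x$readings),
              paste(unique(x$readings$sensor), collapse = ", "),
              nrow(x$events),
              if (nrow(x$events)) paste(unique(x$events$sensor), collapse = ", ")
              else "none"))
  invisible(x)
}

#' Diagnose cadence gaps, duplicates and implausible values in a trace
#'
#' Reports, without repairing, three kinds of problems: missing minutes in a
#' periodic channel's one-per-minute cadence (one diagnostic per contiguous
#' gap), duplicated sensor/minute readings, and values outside the channel's
#' plausibility bounds (temperature -20..60 degC, humidity/light 0..100 %,
#' pressure 850..1100 hPa, gas level >= 0). Repair policy is left to the
#' caller.
#'
#' @param trace A [daily_trace()].
#' @return Tibble with columns `type` ("gap", "duplicate", "out_of_bounds"),
#'   `sensor`, `minute` (first affected minute) and `detail`. Zero rows for a
#'   well-formed day.
#' @export
validate_trace <- function(trace) {
  stopifnot(inherits(trace, "daily_trace"))
  out <- list()
  add <- function(type, sensor, minute, detail) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      type = type, sensor = sensor, minute = as.integer(minute), detail = detail)
  }
  r <- trace$readings
  for (s in intersect(periodic_sensors(), unique(r$sensor))) {
    mins <- sort(r$minute[r$sensor == s])
    missing <- setdiff(0:1439, mins)
    if (length(missing)) {
      # contiguous runs of missing minutes
      brk <- c(0L, which(diff(missing) > 1L), length(missing))
      for (i in seq_len(length(brk) - 1L)) {
        run <- missing[(brk[i] + 1L):brk[i + 1L]]
        add("gap", s, run[1L],
            sprintf("no readings for minutes %s-%s", fmt_hm(run[1L]),
                    fmt_hm(run[length(run)])))
      }
    }
    dup <- unique(mins[duplicated(mins)])
    for (m in dup) add("duplicate", s, m, sprintf("multiple readings at %s", fmt_hm(m)))
    b <- .sensor_bounds[[s]]
    vals <- r[r$sensor == s, ]
    oob <- which(vals$value < b[1] | vals$value > b[2])
    for (i in oob) {
      add("out_of_bounds", s, vals$minute[i],
          sprintf("value %.2f outside [%g, %g]", vals$value[i], b[1], b[2]))
    }
  }
  e <- trace$events
  if (nrow(e)) {
    bad <- setdiff(unique(e$sensor), event_sensors())
    for (s in bad) add("out_of_bounds", s, e$minute[e$sensor == s][1L], "unknown event sensor")
  }
  if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(type = character(0), sensor = character(0),
                   minute = integer(0), detail = character(0))
  }
}
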