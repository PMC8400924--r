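.iso_ts <- function(date, minute) {
  format(as.POSIXct(as.numeric(date) * 86400 + minute * 60,
                    origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%SZ")
}

.parse_ts <- function(x) {
  ts <- as.POSIXct(x, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                                  "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M"))
  if (any(is.na(ts))) stop("unparseable timestamp(s): ",
                           paste(utils::head(x[is.na(ts)], 3), collapse = ", "))
  ts
}

#' Write daily traces to CSV or JSONL files
#'
#' One file per day (`trace_<date>.csv` / `.jsonl`) in the trace dialect:
#' columns `timestamp` (ISO-8601, UTC), `sensor`, `record_type`
#' (`"periodic"` or `"event"`) and `value` (empty for events).
#'
#' @param traces A [daily_trace()] or list of them.
#' @param dir Output directory (created if missing).
#' @param format `"csv"` or `"jsonl"`.
#' @return Invisibly, the paths written.
#' @export
write_traces <- function(traces, dir, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (inherits(traces, "daily_trace")) traces <- list(traces)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (tr in traces) {
    rows <- dplyr::bind_rows(
      tibble::tibble(timestamp = .iso_ts(tr$date, tr$readings$minute),
                     sensor = tr$readings$sensor, record_type = "periodic",
                     value = tr$readings$value),
      tibble::tibble(timestamp = .iso_ts(tr$date, tr$events$minute),
                     sensor = tr$events$sensor, record_type = "event",
                     value = NA_real_))
    rows <- rows[order(rows$timestamp, rows$record_type, rows$sensor), ]
    path <- file.path(dir, sprintf("trace_%s.%s", format(tr$date), format))
    if (format == "csv") {
      readr::write_csv(rows, path, na = "")
    } else {
      con <- file(path, "w")
      for (i in seq_len(nrow(rows))) {
        rec <- list(timestamp = rows$timestamp[i], sensor = rows$sensor[i],
                    record_type = rows$record_type[i])
        if (!is.na(rows$value[i])) rec$value <- rows$value[i]
        writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
      }
      close(con)
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}

.read_trace_rows <- function(path) {
  if (grepl("\\.jsonl$", path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    recs <- lapply(lines, jsonlite::fromJSON)
    tibble::tibble(
      timestamp = vapply(recs, `[[`, character(1), "timestamp"),
      sensor = vapply(recs, `[[`, character(1), "sensor"),
      record_type = vapply(recs, `[[`, character(1), "record_type"),
      value = vapply(recs, function(r) as.numeric(r$value %||% NA_real_), numeric(1)))
  } else {
    readr::read_csv(path, col_types = readr::cols(
      timestamp = readr::col_character(), sensor = readr::col_character(),
      record_type = readr::col_character(), value = readr::col_double()),
      progress = FALSE)
  }
}

#' Read daily traces from CSV/JSONL files
#'
#' `path` may be a single file or a directory of `*.csv` / `*.jsonl` files;
#' rows are grouped by calendar date (rows for the same date coming from
#' different files are merged into a single trace). The dialect is checked
#' strictly: unknown sensors, unknown record types, event rows carrying a
#' value, periodic rows missing one, and temperature values outside the
#' plausible -20..60 degC ingestion bound are errors.
#'
#' @param path File or directory.
#' @return List of [daily_trace()]s sorted by date.
#' @export
read_traces <- function(path) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.(csv|jsonl)$", full.names = TRUE)
  } else path
  if (!length(files)) stop("no trace files found under ", path)
  rows <- dplyr::bind_rows(lapply(sort(files), .read_trace_rows))
  bad_type <- !rows$record_type %in% c("periodic", "event")
  if (any(bad_type)) stop("unknown record_type: ",
                          paste(unique(rows$record_type[bad_type]), collapse = ", "))
  bad_sensor <- !rows$sensor %in% sensor_kinds()
  if (any(bad_sensor)) stop("unknown sensor name: ",
                            paste(unique(rows$sensor[bad_sensor]), collapse = ", "))
  ev <- rows$record_type == "event"
  if (any(ev & !is.na(rows$value))) {
    stop("event rows must not carry a value (",
         sum(ev & !is.na(rows$value)), " offending rows)")
  }
  if (any(!ev & is.na(rows$value))) stop("periodic rows must carry a value")
  if (any(ev & !rows$sensor %in% event_sensors())) {
    stop("record_type=event used with a periodic sensor")
  }
  if (any(!ev & !rows$sensor %in% periodic_sensors())) {
    stop("record_type=periodic used with an event sensor")
  }
  tmp <- !ev & rows$sensor == "temperature"
  b <- .sensor_bounds$temperature
  if (any(tmp & (rows$value < b[1] | rows$value > b[2]))) {
    stop("temperature reading outside plausible bounds [", b[1], ", ", b[2], "]")
  }
  ts <- .parse_ts(rows$timestamp)
  rows$date <- as.Date(ts, tz = "UTC")
  rows$minute <- as.integer(format(ts, "%H", tz = "UTC")) * 60L +
    as.integer(format(ts, "%M", tz = "UTC"))
  out <- lapply(split(rows, rows$date), function(dd) {
    ev <- dd$record_type == "event"
    daily_trace(dd$date[1L],
                readings = dd[!ev, c("minute", "sensor", "value")],
                events = dd[ev, c("minute", "sensor")])
  })
  out[order(as.Date(names(out)))]
}

#' Append alerts to a CSV alert log
#'
#' Creates the file (with header) if needed; on re-runs, rows whose
#' timestamp does not follow the last logged timestamp are skipped, so
#' replaying the same alerts is idempotent.
#'
#' @param alerts Alert tibble (sorted by timestamp) as produced by
#'   [run_day()].
#' @param path Output CSV path.
#' @return Invisibly, the number of rows appended.
#' @export
write_alert_log <- function(alerts, path) {
  if (nrow(alerts) && is.unsorted(alerts$timestamp)) {
    stop("alerts must be sorted by timestamp")
  }
  rows <- tibble::tibble(
    timestamp = format(alerts$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    rule_id = alerts$rule_id, severity = alerts$severity,
    message = alerts$message)
  if (file.exists(path)) {
    old <- readr::read_csv(path, col_types = "cccc", progress = FALSE)
    if (nrow(old)) rows <- rows[rows$timestamp > max(old$timestamp), ]
    readr::write_csv(rows, path, append = TRUE)
  } else {
    readr::write_csv(rows, path)
  }
  invisible(nrow(rows))
}

#' Read an alert log written by [write_alert_log()]
#'
#' @param path CSV path.
#' @return Alert tibble with `timestamp`, `date`, `minute`, `rule_id`,
#'   `severity`, `message`.
#' @export
read_alert_log <- function(path) {
  rows <- readr::read_csv(path, col_types = "cccc", progress = FALSE)
  ts <- if (nrow(rows)) .parse_ts(rows$timestamp)
        else as.POSIXct(character(0), tz = "UTC")
  tibble::tibble(
    timestamp = ts,
    date = as.Date(ts, tz = "UTC"),
    minute = if (nrow(rows)) as.integer(format(ts, "%H", tz = "UTC")) * 60L +
      as.integer(format(ts, "%M", tz = "UTC")) else integer(0),
    rule_id = rows$rule_id, severity = rows$severity, message = rows$message)
}

# ---- ruleset and profile snapshots ----------------------------------------

.rule_to_list <- function(x) {
  if (inherits(x, "hs_rule")) {
    list(record = "rule", rule_id = x$rule_id, kind = x$kind, sensor = x$sensor,
         mutability = x$mutability, threshold = x$threshold, delta = x$delta,
         ranges = lapply(x$ranges, function(r) c(r[[1L]], r[[2L]])),
         day_window = c(x$day_window[[1L]], x$day_window[[2L]]),
         weekdays = x$weekdays, enabled = x$enabled)
  } else {
    list(record = "meta_rule", meta_id = x$meta_id, components = x$components,
         coincidence_window_min = x$coincidence_window_min,
         severity = x$severity, suppress_components = x$suppress_components,
         mutability = x$mutability)
  }
}

#' Write / read a ruleset as JSON
#'
#' @param ruleset List of rules and meta-rules.
#' @param path JSON file path.
#' @return `write_ruleset()`: the path, invisibly. `read_ruleset()`: the
#'   ruleset.
#' @export
write_ruleset <- function(ruleset, path) {
  jsonlite::write_json(lapply(ruleset, .rule_to_list), path,
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_ruleset
#' @export
read_ruleset <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(x) {
    if (identical(x$record, "rule")) {
      rule(x$rule_id, x$kind, x$sensor, mutability = x$mutability,
           threshold = x$threshold, delta = x$delta,
           ranges = lapply(x$ranges, function(r) make_time_range(r[[1]], r[[2]])),
           day_window = make_time_range(x$day_window[[1]], x$day_window[[2]]),
           weekdays = if (!is.null(x$weekdays)) unlist(x$weekdays),
           enabled = isTRUE(x$enabled))
    } else if (identical(x$record, "meta_rule")) {
      meta_rule(x$meta_id, x$components,
                coincidence_window_min = x$coincidence_window_min,
                severity = x$severity,
                suppress_components = isTRUE(x$suppress_components),
                mutability = x$mutability)
    } else stop("unknown ruleset record type")
  })
}

#' Write / read a behaviour-profile snapshot as JSON
#'
#' @param profile A [new_profile()].
#' @param path JSON file path.
#' @return `write_profile()`: the path, invisibly. `read_profile()`: the
#'   profile.
#' @export
write_profile <- function(profile, path) {
  jsonlite::write_json(list(
    sensor = profile$sensor, bin_width = profile$bin_width,
    days_observed = profile$days_observed, counts = profile$counts,
    per_weekday_counts = apply(profile$per_weekday_counts, 1L, identity,
                               simplify = FALSE),
    dates = profile$dates), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  p <- new_profile(raw$sensor, raw$bin_width)
  p$days_observed <- as.integer(raw$days_observed)
  p$counts <- as.integer(raw$counts)
  m <- do.call(rbind, raw$per_weekday_counts)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(weekday = 1:7, NULL)
  p$per_weekday_counts <- m
  p$dates <- as.character(raw$dates)
  p
}

#' Run configuration with defaults
#'
#' Reads a YAML or JSON configuration file holding `engine` and `learning`
#' sections (any subset of [engine_config()] / [learning_config()]
#' arguments) and merges it over the defaults. `read_run_config(NULL)`
#' returns pure defaults.
#'
#' @param path YAML/JSON file, or `NULL`.
#' @return `list(engine = engine_config, learning = learning_config)`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list()
         else if (grepl("\\.json$", path)) jsonlite::fromJSON(path)
         else yaml::read_yaml(path)
  eng <- do.call(engine_config, raw$engine %||% list())
  lrn <- do.call(learning_config, raw$learning %||% list())
  list(engine = eng, learning = lrn)
}

#' Tabulate triggered events against emitted alerts in half-hour windows
#'
#' Reproduces the alert-ledger presentation used to audit the engine: the
#' day is divided into `bin_width`-minute ranges; for each sensor of
#' interest the table reports how many events were triggered in the range
#' and how many alert messages were sent; ranges with no activity at all
#' are omitted.
#'
#' @param traces A [daily_trace()] or list of them.
#' @param alerts Alert tibble.
#' @param sensors Event sensors to tabulate.
#' @param alert_map Named list mapping each sensor to the alert `rule_id`s
#'   that report it (defaults cover the default ruleset: gas to the
#'   gas-presence rule; fire to the plain fire rule and the fire +
#'   temperature meta-rule).
#' @param bin_width Window width in minutes (default 30).
#' @return Tibble with `range` label plus `<sensor>_events` and
#'   `<sensor>_alerts` columns.
#' @export
alert_report <- function(traces, alerts,
                         sensors = c("fire", "gas_presence"),
                         alert_map = list(fire = c("fire", "meta_fire_temp"),
                                          gas_presence = "gas",
                                          motion = NULL, tv_remote = NULL),
                         bin_width = 30L) {
  if (inherits(traces, "daily_trace")) traces <- list(traces)
  nb <- ceiling(1440L / bin_width)
  out <- tibble::tibble(bin = 0:(nb - 1L),
                        range = sprintf("%s-%s", fmt_hm((0:(nb - 1L)) * bin_width),
                                        fmt_hm(pmin((1:nb) * bin_width, 1440L))))
  events <- dplyr::bind_rows(lapply(traces, `[[`, "events"))
  for (s in sensors) {
    emins <- events$minute[events$sensor == s]
    out[[paste0(s, "_events")]] <- tabulate(emins %/% bin_width + 1L, nbins = nb)
    ids <- alert_map[[s]]
    if (is.null(ids)) {
      # fall back: any rule id mentioning the sensor name
      ids <- unique(alerts$rule_id[grepl(sub("_presence$", "", s), alerts$rule_id)])
    }
    amins <- alerts$minute[alerts$rule_id %in% ids]
    out[[paste0(s, "_alerts")]] <- tabulate(amins %/% bin_width + 1L, nbins = nb)
  }
  act <- rowSums(as.matrix(out[, -(1:2)])) > 0
  out[act, ]
}
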