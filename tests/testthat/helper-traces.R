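# Shared builders for compact test traces.

# a full-cadence temperature-only day (other channels omitted)
temp_day <- function(date, values) {
  stopifnot(length(values) == 1440L)
  daily_trace(date, readings = tibble::tibble(
    minute = 0:1439, sensor = "temperature", value = values))
}

# constant periodic channels + caller-supplied events
quiet_day <- function(date, events = NULL, temp = 20, light_day = 60) {
  light <- rep(0, 1440L)
  light[481:1080] <- light_day
  light[1081:1380] <- 40
  daily_trace(date, readings = tibble::tibble(
    minute = rep(0:1439, 2L),
    sensor = rep(c("temperature", "light"), each = 1440L),
    value = c(rep(temp, 1440L), light)),
    events = events)
}

motion_events <- function(minutes) {
  tibble::tibble(minute = as.integer(minutes), sensor = "motion")
}

# a resident whose schedule aligns exactly with hour bins
hourly_resident <- function(wake_h = 8L, sleep_h = 23L, ...) {
  resident_config(wake = sprintf("%02d:00", wake_h),
                  sleep = sprintf("%02d:00", sleep_h), ...)
}

count_rule <- function(alerts, ids) sum(alerts$rule_id %in% ids)
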