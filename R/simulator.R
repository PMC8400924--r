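#' Synthetic resident configuration
#'
#' Describes the daily routine and home environment the simulator emulates:
#' an active period between `wake` and `sleep` during which motion events
#' arrive as a Poisson process, evening TV use, a diurnal temperature curve
#' with optional heating episodes, and a three-level light profile
#' (day / evening / night). Weekday-specific away windows silence motion
#' and TV (the resident is out of the home).
#'
#' @param wake,sleep "HH:MM" strings or minutes; the active period is
#'   `[wake, sleep)` and must not wrap midnight.
#' @param motion_rate Motion events per hour while active (default 20).
#' @param tv_windows List of time ranges of TV use (default 20:00-23:00).
#' @param tv_rate TV-remote events per hour within the TV windows.
#' @param away_windows List of `list(weekday =, range =)` entries (ISO
#'   weekday, 1 = Monday) during which motion and TV are silenced.
#' @param temp_base,temp_amplitude Baseline (degC) and diurnal amplitude of
#'   the temperature curve (coldest 04:00, warmest 16:00).
#' @param heating_windows List of `list(range =, setpoint =)` heating
#'   episodes; the temperature ramps to the setpoint and holds it.
#' @param light_day,light_evening,light_night Light levels in % for the
#'   day (`[wake, 18:00)`), evening (`[18:00, sleep)`) and night periods.
#'   Defaults (60 / 40 / 0) keep the default light rules quiet.
#' @param noise_sd Named list of per-channel Gaussian noise SDs. The
#'   temperature default (0.05 degC) is far below the 2 degC rise rule, so
#'   noise never triggers it.
#' @param seed Default master seed used when [simulate_day()] is not given
#'   one explicitly.
#' @return A list of class `resident_config`.
#' @export
resident_config <- function(wake = "08:00", sleep = "23:00",
                            motion_rate = 20, tv_windows = NULL, tv_rate = 30,
                            away_windows = list(),
                            temp_base = 19, temp_amplitude = 3,
                            heating_windows = list(),
                            light_day = 60, light_evening = 40, light_night = 0,
                            noise_sd = list(), seed = 1L) {
  to_min <- function(x) if (is.character(x)) parse_hm(x) else as.integer(x)
  wake <- to_min(wake); sleep <- to_min(sleep)
  if (!(wake >= 0L && wake < sleep && sleep <= 1440L)) {
    stop("need 0 <= wake < sleep <= 1440")
  }
  if (is.null(tv_windows)) tv_windows <- list(make_time_range(1200, 1380))
  stopifnot(motion_rate >= 0, tv_rate >= 0, temp_amplitude >= 0)
  ns <- list(temperature = 0.05, humidity = 0.5, pressure = 0.3,
             light = 0.2, gas_level = 0.01)
  ns[names(noise_sd)] <- noise_sd
  structure(list(wake = wake, sleep = sleep, motion_rate = motion_rate,
                 tv_windows = tv_windows, tv_rate = tv_rate,
                 away_windows = away_windows, temp_base = temp_base,
                 temp_amplitude = temp_amplitude,
                 heating_windows = heating_windows,
                 light_day = light_day, light_evening = light_evening,
                 light_night = light_night, noise_sd = ns,
                 seed = as.integer(seed)),
            class = "resident_config")
}

# evaluate expr under a temporary RNG seed, restoring the caller's stream
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# one named RNG stream per channel, derived from (master seed, date,
# channel), so adding a channel never perturbs the others
.channel_seed <- function(seed, date, channel) {
  idx <- match(channel, c(periodic_sensors(), "motion", "tv_remote"))
  as.integer((as.numeric(seed) * 7919 + (as.numeric(date) %% 65536) * 131 +
                idx * 65537) %% 2147483629)
}

.active_mask <- function(cfg, weekday) {
  mask <- rep(FALSE, 1440L)
  mask[(cfg$wake + 1L):cfg$sleep] <- TRUE
  for (aw in cfg$away_windows) {
    if (aw$weekday == weekday) mask <- mask & !range_mask(list(aw$range))
  }
  mask
}

.poisson_events <- function(mask, rate_per_hour, seed, sensor) {
  counts <- .with_seed(seed, stats::rpois(1440L, (rate_per_hour / 60) * mask))
  mins <- rep(0:1439, counts)
  tibble::tibble(minute = as.integer(mins), sensor = rep(sensor, length(mins)))
}

#' Simulate one day of resident behaviour and home environment
#'
#' Produces a full [daily_trace()]: per-minute readings on all five
#' periodic channels and Poisson motion / TV-remote events inside the
#' configured windows (none outside; away windows silence both). The
#' temperature is the diurnal curve plus heating pull plus Gaussian noise.
#' Output is deterministic in `(cfg, date, seed)`.
#'
#' @param cfg A [resident_config()].
#' @param date Date of the simulated day.
#' @param seed Master seed (defaults to `cfg$seed`).
#' @return A [daily_trace()].
#' @export
simulate_day <- function(cfg, date, seed = cfg$seed) {
  stopifnot(inherits(cfg, "resident_config"), inherits(date, "Date"))
  m <- 0:1439
  wd <- .iso_weekday(date)

  temp <- cfg$temp_base + cfg$temp_amplitude * sin(2 * pi * (m - 600) / 1440)
  for (hw in cfg$heating_windows) {
    s <- hw$range[[1L]]; en <- hw$range[[2L]]
    start_val <- temp[max(s, 1L)]
    ramp_len <- min(10L, en - s)
    for (j in seq_len(en - s)) {
      i <- s + j          # 1-based index of minute s + j - 1
      target <- hw$setpoint
      temp[i] <- if (j <= ramp_len) {
        start_val + (target - start_val) * j / ramp_len
      } else target
    }
    rel_len <- min(30L, 1440L - en)
    if (rel_len > 0L) {
      for (j in seq_len(rel_len)) {
        i <- en + j
        base_v <- cfg$temp_base +
          cfg$temp_amplitude * sin(2 * pi * ((i - 1L) - 600) / 1440)
        temp[i] <- hw$setpoint + (base_v - hw$setpoint) * j / rel_len
      }
    }
  }
  temp <- temp + .with_seed(.channel_seed(seed, date, "temperature"),
                            stats::rnorm(1440L, 0, cfg$noise_sd$temperature))

  light <- rep(cfg$light_night, 1440L)
  day_end <- min(1080L, cfg$sleep)
  if (cfg$wake < day_end) light[(cfg$wake + 1L):day_end] <- cfg$light_day
  if (cfg$sleep > 1080L) light[1081L:cfg$sleep] <- cfg$light_evening
  light <- light + .with_seed(.channel_seed(seed, date, "light"),
                              stats::rnorm(1440L, 0, cfg$noise_sd$light))
  light <- pmin(pmax(light, 0), 100)

  humidity <- pmin(pmax(45 + .with_seed(.channel_seed(seed, date, "humidity"),
                                        stats::rnorm(1440L, 0, cfg$noise_sd$humidity)),
                        0), 100)
  pressure <- 1013 + .with_seed(.channel_seed(seed, date, "pressure"),
                                stats::rnorm(1440L, 0, cfg$noise_sd$pressure))
  gas_level <- pmax(0.05 + .with_seed(.channel_seed(seed, date, "gas_level"),
                                      stats::rnorm(1440L, 0, cfg$noise_sd$gas_level)),
                    0)

  readings <- tibble::tibble(
    minute = rep(m, 5L),
    sensor = rep(periodic_sensors(), each = 1440L),
    value = c(temp, humidity, pressure, light, gas_level))

  act <- .active_mask(cfg, wd)
  tvmask <- range_mask(cfg$tv_windows) & act
  events <- dplyr::bind_rows(
    .poisson_events(act, cfg$motion_rate, .channel_seed(seed, date, "motion"), "motion"),
    .poisson_events(tvmask, cfg$tv_rate, .channel_seed(seed, date, "tv_remote"), "tv_remote"))

  daily_trace(date, readings, events)
}

#' Simulate a period of consecutive days
#'
#' Per-day randomness is drawn from streams derived from
#' `(seed, date, channel)`, so any day of the period can be regenerated in
#' isolation.
#'
#' @param cfg A [resident_config()].
#' @param start_date First date.
#' @param n_days Number of consecutive days (>= 1).
#' @param seed Master seed.
#' @return List of [daily_trace()]s.
#' @export
simulate_period <- function(cfg, start_date, n_days, seed = cfg$seed) {
  n_days <- as.integer(n_days)
  if (is.na(n_days) || n_days < 1L) stop("n_days must be >= 1")
  lapply(seq_len(n_days) - 1L, function(i) {
    simulate_day(cfg, start_date + i, seed)
  })
}

#' Specify an anomaly to inject into a simulated day
#'
#' Kinds: `gas_event` and `fire_event` append events at minute(s) `at`;
#' `temp_spike` rewrites the temperature so a rise of at least
#' `magnitude` (>= 2) degC between consecutive minutes completes exactly at
#' `at`, followed by a slow decay; `nocturnal_motion` adds motion events
#' every 5 minutes inside `range`; `daytime_absence` deletes all motion
#' events inside `range`; `heating_left_on` holds the temperature
#' `magnitude` degC above the day's 09:00-16:00 maximum throughout `range`
#' (entered with a ramp that stays below the rise rule's threshold).
#'
#' @param kind One of the kinds above.
#' @param at Minute of day (or "HH:MM") for point anomalies.
#' @param range A [make_time_range()] for ranged anomalies.
#' @param magnitude Optional size (degC).
#' @return A list of class `anomaly_spec`.
#' @export
anomaly_spec <- function(kind, at = NULL, range = NULL, magnitude = NULL) {
  kind <- match.arg(kind, c("gas_event", "fire_event", "nocturnal_motion",
                            "daytime_absence", "temp_spike", "heating_left_on"))
  if (!is.null(at) && is.character(at)) at <- parse_hm(at)
  point_kinds <- c("gas_event", "fire_event", "temp_spike")
  if (kind %in% point_kinds && is.null(at)) stop(kind, " needs `at`")
  if (!kind %in% point_kinds && is.null(range)) stop(kind, " needs `range`")
  structure(list(kind = kind, at = at, range = range, magnitude = magnitude),
            class = "anomaly_spec")
}

# replace the value column of one periodic channel, given a full-cadence vector
.set_channel <- function(trace, sensor, values) {
  idx <- trace$readings$sensor == sensor
  stopifnot(sum(idx) == 1440L)
  ord <- order(trace$readings$minute[idx])
  v <- trace$readings$value
  v[which(idx)[ord]] <- values
  trace$readings$value <- v
  trace
}

.get_channel <- function(trace, sensor) {
  idx <- trace$readings$sensor == sensor
  stopifnot(sum(idx) == 1440L)
  trace$readings$value[idx][order(trace$readings$minute[idx])]
}

#' Inject an anomaly into a daily trace
#'
#' Returns a new trace with the anomaly merged; records outside the
#' anomaly's channel and scope are untouched. Injecting an event at a
#' minute where an identical event already exists is an idempotent merge.
#'
#' @param trace A [daily_trace()].
#' @param spec An [anomaly_spec()].
#' @return Modified [daily_trace()].
#' @export
inject_anomaly <- function(trace, spec) {
  stopifnot(inherits(trace, "daily_trace"), inherits(spec, "anomaly_spec"))
  add_events <- function(trace, sensor, minutes) {
    have <- trace$events$minute[trace$events$sensor == sensor]
    minutes <- setdiff(as.integer(minutes), have)
    if (length(minutes)) {
      trace$events <- dplyr::bind_rows(
        trace$events, tibble::tibble(minute = minutes, sensor = sensor))
    }
    daily_trace(trace$date, trace$readings, trace$events)
  }
  switch(spec$kind,
    gas_event = add_events(trace, "gas_presence", spec$at),
    fire_event = add_events(trace, "fire", spec$at),
    nocturnal_motion = add_events(trace, "motion",
                                  seq(spec$range[[1L]], spec$range[[2L]] - 1L, by = 5L)),
    daytime_absence = {
      drop <- trace$events$sensor == "motion" &
        in_range(trace$events$minute, spec$range)
      trace$events <- trace$events[!drop, ]
      daily_trace(trace$date, trace$readings, trace$events)
    },
    temp_spike = {
      v <- .get_channel(trace, "temperature")
      amt <- max(2, spec$magnitude %||% 2.5)
      tail_len <- 45L
      for (j in 0:(tail_len - 1L)) {
        i <- spec$at + 1L + j
        if (i > 1440L) break
        v[i] <- v[i] + amt * (1 - j / tail_len)
      }
      .set_channel(trace, "temperature", v)
    },
    heating_left_on = {
      v <- .get_channel(trace, "temperature")
      day_max <- max(v[541:960])
      target <- day_max + (spec$magnitude %||% 0.5)
      s <- spec$range[[1L]]; en <- spec$range[[2L]]
      for (j in seq_len(en - s)) {
        i <- s + j
        ramped <- v[max(s, 1L)] + 1.5 * j       # entry ramp below the 2 degC rule
        v[i] <- max(v[i], min(target, ramped))
      }
      .set_channel(trace, "temperature", v)
    })
}

# ---- deterministic worked-example fixtures --------------------------------

# benign background shared by the fixtures: quiet constant channels, a
# three-level light profile and regular daytime motion, chosen so that no
# rule other than the one under study fires
.fixture_background <- function(date, temp) {
  m <- 0:1439
  light <- rep(0, 1440L)
  light[481:1080] <- 60      # 08:00-18:00
  light[1081:1260] <- 40     # 18:00-21:00 (above the 20 % evening floor)
  light[1261:1380] <- 10     # 21:00-23:00
  readings <- tibble::tibble(
    minute = rep(m, 5L),
    sensor = rep(periodic_sensors(), each = 1440L),
    value = c(temp, rep(45, 1440L), rep(1013, 1440L), light, rep(0.05, 1440L)))
  events <- tibble::tibble(minute = as.integer(seq(480L, 1379L, by = 15L)),
                           sensor = "motion")
  daily_trace(date, readings, events)
}

# piecewise-linear curve through (minute, value) nodes
.pw_linear <- function(nodes_min, nodes_val) {
  stats::approx(nodes_min, nodes_val, xout = 0:1439, rule = 2)$y
}

#' Deterministic fixture: the intentional-alteration day
#'
#' Encodes the worked example of a day on which the room environment was
#' deliberately disturbed: fire detections at 13:39, 13:40 and 21:56 (plus
#' further detections spread over the late morning and early afternoon), gas
#' detections in eleven half-hour windows including the printed 13:56 (which
#' is alerted) and 14:29 (which the cooldown swallows), and three abrupt
#' temperature rises whose qualifying 2 degC consecutive-minute pairs
#' complete at 14:00, 19:36 and 21:59. Within the 21:54-21:59 rise the only
#' pair gaining at least 1 degC before the final one completes at 21:57 --
#' one minute after the 21:56 fire detection -- so the fire + temperature
#' meta-rule fires exactly once, at 21:57. Unprinted event times are fixed
#' deterministically so the whole day's alert accounting follows from the
#' cooldown arithmetic.
#'
#' @param date Date to stamp on the trace.
#' @return A [daily_trace()].
#' @export
fixture_fire_day <- function(date = as.Date("2021-03-16")) {
  temp <- rep(20, 1440L)
  add_spike <- function(temp, incr_minutes, incrs, decay_to = 20, decay_len = 60L) {
    for (k in seq_along(incr_minutes)) {
      i <- incr_minutes[k] + 1L
      temp[i:1440L] <- temp[i:1440L] + incrs[k]
    }
    peak_min <- incr_minutes[length(incr_minutes)]
    peak_val <- temp[peak_min + 1L]
    for (j in seq_len(decay_len)) {
      i <- peak_min + 1L + j
      if (i > 1440L) break
      temp[i] <- peak_val + (decay_to - peak_val) * j / decay_len
    }
    if (peak_min + 1L + decay_len < 1440L) {
      temp[(peak_min + 2L + decay_len):1440L] <- decay_to
    }
    temp
  }
  # 13:51-14:00 rise: +0.5/min, then +2.0 completing at 14:00
  temp <- add_spike(temp, parse_hm("13:52") + 0:8,
                    c(rep(0.5, 8), 2.0))
  # 19:29-19:36 rise: +0.5/min, then +2.0 completing at 19:36
  temp <- add_spike(temp, parse_hm("19:30") + 0:6,
                    c(rep(0.5, 6), 2.0))
  # 21:54-21:59 rise: first pair >= 1 degC completes at 21:57, the
  # qualifying >= 2 degC pair at 21:59
  temp <- add_spike(temp, parse_hm("21:55") + 0:4,
                    c(0.9, 0.9, 1.0, 0.9, 2.0))

  tr <- .fixture_background(date, temp)
  gas <- parse_hm(c("12:05", "12:10", "12:15",
                    "13:00", "13:05", "13:10", "13:15",
                    "13:56", "13:57", "13:58", "13:59",
                    "14:05", "14:29",
                    "14:35", "14:40",
                    "15:35", "15:40",
                    "17:05", "17:10", "17:15",
                    "18:35", "18:40",
                    "20:40", "20:45",
                    "21:05", "21:10",
                    "21:46", "21:50"))
  fire <- c(parse_hm("11:45"),
            parse_hm("12:31") + 0:8,
            parse_hm("13:02") + 3L * (0:5),
            parse_hm(c("13:39", "13:40", "14:15", "14:45",
                       "21:31", "21:35", "21:56")))
  tr$events <- dplyr::bind_rows(
    tr$events,
    tibble::tibble(minute = as.integer(gas), sensor = "gas_presence"),
    tibble::tibble(minute = as.integer(fire), sensor = "fire"))
  daily_trace(date, tr$readings, tr$events)
}

#' Deterministic fixture: bedtime-temperature worked example
#'
#' Two consecutive days exercising the bedtime-vs-daytime rule. Day one's
#' afternoon reaches a 21.8 degC maximum; in the following early morning
#' the temperature touches 21.9 degC at exactly 02:01 and 03:33 (heating
#' left on while the resident stayed up), every other night minute staying
#' below the stored maximum -- two alerts. Day two's afternoon reaches
#' 23.8 degC and the temperature then holds 23.9 degC from 23:17 to 23:32
#' (heating left on in bed); the cooldown turns the sustained exceedance
#' into a single alert at 23:17. Three alerts in total.
#'
#' @param start_date Date of the first day (a Wednesday by default).
#' @return List of two [daily_trace()]s.
#' @export
fixture_night_temp <- function(start_date = as.Date("2021-03-03")) {
  day_a <- .pw_linear(c(0, 240, 840, 1200, 1439),
                      c(20.0, 19.0, 21.8, 21.0, 20.4))
  day_b <- .pw_linear(c(0, 240, 840, 1200, 1439),
                      c(20.4, 19.4, 23.8, 22.4, 22.0))
  # early-morning heating episodes: discrete instants at 02:01 and 03:33
  day_b[parse_hm("02:00") + 1L] <- 20.5
  day_b[parse_hm("02:01") + 1L] <- 21.9
  day_b[parse_hm("02:02") + 1L] <- 20.5
  day_b[parse_hm("03:32") + 1L] <- 20.4
  day_b[parse_hm("03:33") + 1L] <- 21.9
  day_b[parse_hm("03:34") + 1L] <- 20.5
  # heating left on in bed: sustained 23.9 degC from 23:17 to 23:32
  day_b[(parse_hm("23:17") + 1L):(parse_hm("23:32") + 1L)] <- 23.9
  list(.fixture_background(start_date, day_a),
       .fixture_background(start_date + 1L, day_b))
}
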