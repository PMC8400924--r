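#' Engine configuration
#'
#' Tunables of the alert engine. `cooldown_min` is the minimum spacing, in
#' minutes, between successive alerts of the same type (default 30; see
#' [cooldown_gate()] for the exact gating semantics).
#' `coincidence_window_min` is the trailing window within which the two
#' components of a meta-rule must co-occur (default 10).
#' `fire_plain_rule_enabled` restores the literal stand-alone fire-presence
#' rule; by default fire alerts are sent only by the fire + temperature-rise
#' meta-rule, because a flame sensor alone is prone to false positives.
#'
#' @param cooldown_min Integer minutes; 0 disables throttling.
#' @param coincidence_window_min Integer minutes.
#' @param fire_plain_rule_enabled Logical.
#' @return A list of class `engine_config`.
#' @export
engine_config <- function(cooldown_min = 30L, coincidence_window_min = 10L,
                          fire_plain_rule_enabled = FALSE) {
  stopifnot(cooldown_min >= 0L, coincidence_window_min >= 0L)
  structure(list(cooldown_min = as.integer(cooldown_min),
                 coincidence_window_min = as.integer(coincidence_window_min),
                 fire_plain_rule_enabled = isTRUE(fire_plain_rule_enabled)),
            class = "engine_config")
}

#' Create a fresh engine state
#'
#' The engine state bundles the ruleset, the life-cycle phase, the cooldown
#' registry, the stored daytime temperature maximum, per-sensor last
#' readings, per-range activity flags for absence rules and the recent
#' component occurrences consumed by the meta-rules. During the
#' `"calibration"` phase the engine updates all of this but emits no alerts.
#'
#' @param ruleset List of rules and meta-rules, see [default_ruleset()].
#' @param config An [engine_config()].
#' @param phase `"calibration"`, `"readjustment"` or `"stable"`.
#' @return An object of class `engine_state`.
#' @export
new_engine_state <- function(ruleset = NULL, config = engine_config(),
                             phase = c("stable", "calibration", "readjustment")) {
  phase <- match.arg(phase)
  if (is.null(ruleset)) {
    ruleset <- default_ruleset(
      fire_plain_rule_enabled = config$fire_plain_rule_enabled,
      coincidence_window_min = config$coincidence_window_min)
  }
  structure(list(
    ruleset = ruleset,
    config = config,
    phase = phase,
    day_index = 0L,
    cooldown = list(),          # key -> absolute minute of last emitted alert
    last_value = stats::setNames(rep(NA_real_, 5L), periodic_sensors()),
    last_minute = stats::setNames(rep(NA_real_, 5L), periodic_sensors()),
    day_max = NA_real_,         # running max temperature over the day window
    day_max_day = NA_integer_,  # day (absolute day number) the max belongs to
    absence_seen = list(),      # "rule_id@start" -> TRUE once activity seen
    stamps = list(),            # meta component key -> absolute minute
    last_processed = -Inf,      # absolute minute of the last processed input
    current_date = as.Date(NA)
  ), class = "engine_state")
}

#' @export
print.engine_state <- function(x, ...) {
  cat(sprintf("<engine_state> phase=%s day_index=%d rules=%d metas=%d cooldown keys=%d\n",
              x$phase, x$day_index, length(ruleset_rules(x$ruleset)),
              length(ruleset_metas(x$ruleset)), length(x$cooldown)))
  invisible(x)
}

# absolute minutes of a date's midnight
.day_abs <- function(date) as.numeric(date) * 1440

# Core of the throttling decision, shared by cooldown_gate() and the engine.
# Emission is assessed at the granularity of wall-clock windows of
# `cd` minutes aligned to midnight: a new alert for a key is allowed only
# when the window containing `now` opened at least `cd` minutes after the
# last emission. This implies both throttling guarantees the alert ledger is
# organised around: at most one alert per key per aligned window, and
# consecutive alerts of the same key at least `cd` minutes apart.
.gate_ok <- function(last, now, cd) {
  if (is.null(last) || cd <= 0L) return(TRUE)
  ((now %/% cd) * cd - last) >= cd
}

#' Cooldown gate: should an alert for this key be emitted now?
#'
#' Alert messages of the same type are throttled so they are not sent twice
#' in a row until the cooldown (default 30 min) has elapsed. Throttling is
#' assessed at the granularity of wall-clock windows of `cooldown_min`
#' minutes aligned to midnight: an alert is allowed only if the window
#' containing `now` opened at least `cooldown_min` minutes after the last
#' emitted alert for the key. Consequences: at most one alert per key is
#' sent per aligned window, and consecutive alerts of the same key are
#' always at least `cooldown_min` minutes apart. An alert sent at 13:56 thus
#' throttles the whole of 14:00-14:30 (that window opened only 4 minutes
#' after the alert), while an event at 14:30 or later passes.
#'
#' @param state An [new_engine_state()] state.
#' @param key Cooldown key (rule id or meta-rule id).
#' @param now Time in absolute minutes (`as.numeric(date) * 1440 + minute`);
#'   any monotone minute clock works as long as it is used consistently.
#' @return `list(emit = logical, state = updated state)`; the registry is
#'   stamped only when `emit` is `TRUE`.
#' @export
cooldown_gate <- function(state, key, now) {
  cd <- state$config$cooldown_min
  ok <- .gate_ok(state$cooldown[[key]], now, cd)
  if (ok) state$cooldown[[key]] <- now
  list(emit = ok, state = state)
}

# ---- single-rule condition primitives -------------------------------------

#' Evaluate a threshold rule against one periodic reading
#'
#' Strict comparisons: a low rule fires when `value < threshold`, a high
#' rule when `value > threshold`; a reading exactly at the threshold never
#' fires.
#'
#' @param rule A `threshold_low` or `threshold_high` [rule()].
#' @param reading List with `minute`, `sensor`, `value`.
#' @return Logical.
#' @export
eval_threshold <- function(rule, reading) {
  if (!rule$kind %in% c("threshold_low", "threshold_high")) {
    stop("eval_threshold() needs a threshold rule")
  }
  if (!identical(rule$sensor, reading$sensor)) {
    stop("sensor mismatch: rule watches ", rule$sensor, ", reading is ", reading$sensor)
  }
  if (rule$kind == "threshold_low") reading$value < rule$threshold
  else reading$value > rule$threshold
}

#' Evaluate a consecutive-minute rise rule
#'
#' Compares the current reading with the reading of the immediately
#' preceding minute; fires when the rise is at least `rule$delta`. Readings
#' separated by a gap are not comparable (the rule is inert across gaps) and
#' passing them is a contract error.
#'
#' @param rule A `delta_rise` [rule()].
#' @param prev,cur Readings (lists with `minute`, `sensor`, `value`) at
#'   consecutive minutes of the same sensor.
#' @return Logical: `cur$value - prev$value >= rule$delta`.
#' @export
eval_delta <- function(rule, prev, cur) {
  if (rule$kind != "delta_rise") stop("eval_delta() needs a delta_rise rule")
  if (!identical(prev$sensor, cur$sensor) || !identical(cur$sensor, rule$sensor)) {
    stop("sensor mismatch in eval_delta()")
  }
  if (cur$minute - prev$minute != 1) {
    stop("eval_delta() requires readings at consecutive minutes")
  }
  (cur$value - prev$value) >= rule$delta
}

#' Update the stored daytime temperature maximum
#'
#' The engine stores the highest temperature observed inside the daytime
#' window (default 09:00-16:00). The stored maximum persists after the
#' window closes -- through the evening, past midnight and into the early
#' morning -- until the next day's window opens, so bedtime checks at e.g.
#' 02:01 compare against the previous afternoon. `date` identifies the day
#' the reading belongs to; the maximum resets when a reading falls inside
#' the window on a later day than the stored one.
#'
#' @param state Engine state.
#' @param reading Temperature reading (list with `minute`, `sensor`, `value`).
#' @param date Date of the reading (defaults to the state's current date).
#' @param day_window The daytime window, a [make_time_range()].
#' @return Updated state.
#' @export
update_day_max <- function(state, reading, date = state$current_date,
                           day_window = make_time_range(540, 960)) {
  if (!identical(reading$sensor, "temperature")) {
    stop("update_day_max() takes temperature readings")
  }
  if (!in_range(reading$minute, day_window)) return(state)
  d <- as.integer(as.numeric(date))
  if (is.na(state$day_max_day) || state$day_max_day != d) {
    state$day_max <- -Inf
    state$day_max_day <- d
  }
  if (reading$value > state$day_max) state$day_max <- reading$value
  state
}

#' Evaluate the bedtime-vs-daytime temperature rule
#'
#' Fires when, at bedtime (the rule's ranges), the current temperature is
#' greater than *or equal to* the stored daytime maximum -- the typical
#' signature of heating left on at night. With no stored maximum (fresh
#' state, first night) the rule is inert.
#'
#' @param rule A `night_vs_day` [rule()].
#' @param state Engine state carrying `day_max`.
#' @param reading Temperature reading.
#' @return Logical.
#' @export
eval_night_vs_day <- function(rule, state, reading) {
  if (rule$kind != "night_vs_day") stop("eval_night_vs_day() needs a night_vs_day rule")
  if (!identical(reading$sensor, "temperature")) stop("sensor mismatch")
  if (!is.finite(state$day_max %||% NA_real_)) return(FALSE)
  in_any_range(reading$minute, rule$ranges) && reading$value >= state$day_max
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an unusual-hours presence rule against one event
#'
#' @param rule A `presence_in_range` [rule()].
#' @param event List with `minute` and `sensor`.
#' @return Logical: the event's sensor matches and its clock falls in one of
#'   the rule's (unusual) ranges.
#' @export
eval_presence <- function(rule, event) {
  if (rule$kind != "presence_in_range") stop("eval_presence() needs a presence rule")
  identical(event$sensor, rule$sensor) && in_any_range(event$minute, rule$ranges)
}

#' Evaluate a usual-hours absence rule at a clock minute
#'
#' An absence is only decidable once its range closes, so the rule is
#' evaluated exactly at the minute the range ends: it fires if no qualifying
#' event was seen inside the range that day. At any other minute (including
#' minutes inside the range) the result is `FALSE`.
#'
#' @param rule An `absence_in_range` [rule()].
#' @param state Engine state carrying the day's activity flags.
#' @param clock Minute of day.
#' @return Logical.
#' @export
eval_absence <- function(rule, state, clock) {
  if (rule$kind != "absence_in_range") stop("eval_absence() needs an absence rule")
  for (r in rule$ranges) {
    if (clock == r[[2L]]) {
      key <- sprintf("%s@%d", rule$rule_id, r[[1L]])
      return(!isTRUE(state$absence_seen[[key]]))
    }
  }
  FALSE
}

# stamp key a meta component reads
.component_key <- function(cp) {
  switch(cp$type,
         event = paste0("ev_", cp$sensor),
         event_in_unusual = paste0("unusual_", cp$sensor),
         temp_rise = sprintf("rise_%g", cp$delta),
         light_low_state = sprintf("lightlow_%g", cp$threshold))
}

#' Evaluate a meta-rule's coincidence condition
#'
#' True exactly when both component conditions occurred within the
#' coincidence window ending at `now` and the later of the two occurred at
#' `now` -- a coincidence therefore fires once, at the minute it completes.
#'
#' @param meta A [meta_rule()].
#' @param state Engine state (its component occurrence stamps must be
#'   current through `now`).
#' @param now Absolute minute.
#' @return Logical.
#' @export
eval_meta <- function(meta, state, now) {
  t1 <- state$stamps[[.component_key(meta$components[[1L]])]]
  t2 <- state$stamps[[.component_key(meta$components[[2L]])]]
  if (is.null(t1) || is.null(t2)) return(FALSE)
  w <- meta$coincidence_window_min
  min(t1, t2) >= now - w && max(t1, t2) == now
}

# ---- compiled per-day evaluation ------------------------------------------

# Pre-resolve the ruleset into flat structures for the minute loop.
# Weekday-specific rules are filtered here, so compilation is per day.
.compile_ruleset <- function(ruleset, weekday, config) {
  rules <- ruleset_rules(ruleset)
  metas <- ruleset_metas(ruleset)
  applies <- function(r) is.null(r$weekdays) || weekday %in% r$weekdays
  cp <- list(th = list(), delta = list(), night = list(), light = list(),
             event = list(), presence = list(), absence = list(),
             metas = list(), rise_deltas = numeric(0),
             lowlight_thresholds = numeric(0),
             unusual_mask = list(), absence_by_sensor = list(),
             daywin = c(540L, 960L))
  for (r in rules) {
    if (!r$enabled || !applies(r)) next
    si <- match(r$sensor, periodic_sensors())
    item <- switch(
      r$kind,
      threshold_low = ,
      threshold_high = list(id = r$rule_id, si = si, lo = r$kind == "threshold_low",
                            thr = r$threshold),
      delta_rise = list(id = r$rule_id, si = si, delta = r$delta),
      night_vs_day = list(id = r$rule_id, mask = range_mask(r$ranges)),
      light_low_in_range = ,
      light_high_in_range = list(id = r$rule_id, mask = range_mask(r$ranges),
                                 lo = r$kind == "light_low_in_range",
                                 thr = r$threshold),
      event_presence = list(id = r$rule_id, sensor = r$sensor),
      presence_in_range = list(id = r$rule_id, sensor = r$sensor,
                               mask = range_mask(r$ranges)),
      absence_in_range = list(id = r$rule_id, sensor = r$sensor,
                              ranges = r$ranges, mask = range_mask(r$ranges))
    )
    slot <- switch(r$kind,
                   threshold_low = "th", threshold_high = "th",
                   delta_rise = "delta", night_vs_day = "night",
                   light_low_in_range = "light", light_high_in_range = "light",
                   event_presence = "event", presence_in_range = "presence",
                   absence_in_range = "absence")
    cp[[slot]][[length(cp[[slot]]) + 1L]] <- item
    if (r$kind == "night_vs_day") cp$daywin <- c(r$day_window[[1L]], r$day_window[[2L]])
  }
  # union of (enabled, applicable) presence masks per sensor = "unusual hours"
  for (p in cp$presence) {
    m <- cp$unusual_mask[[p$sensor]]
    cp$unusual_mask[[p$sensor]] <- if (is.null(m)) p$mask else m | p$mask
  }
  for (a in cp$absence) {
    cp$absence_by_sensor[[a$sensor]] <-
      c(cp$absence_by_sensor[[a$sensor]], list(a))
  }
  for (mt in metas) {
    sup <- character(0)
    for (comp in mt$components) {
      if (comp$type == "event") {
        sup <- c(sup, vapply(cp$event,
                             function(x) if (x$sensor == comp$sensor) x$id else NA_character_,
                             character(1)))
      } else if (comp$type == "event_in_unusual") {
        sup <- c(sup, vapply(cp$presence,
                             function(x) if (x$sensor == comp$sensor) x$id else NA_character_,
                             character(1)))
      } else if (comp$type == "temp_rise") {
        cp$rise_deltas <- unique(c(cp$rise_deltas, comp$delta))
      } else if (comp$type == "light_low_state") {
        cp$lowlight_thresholds <- unique(c(cp$lowlight_thresholds, comp$threshold))
      }
    }
    cp$metas[[length(cp$metas) + 1L]] <- list(
      id = mt$meta_id,
      k1 = .component_key(mt$components[[1L]]),
      k2 = .component_key(mt$components[[2L]]),
      w = mt$coincidence_window_min,
      severity = mt$severity,
      suppress = mt$suppress_components,
      suppress_keys = sup[!is.na(sup)])
  }
  cp
}

# Build a mutable evaluation environment from an immutable state.
.engine_env <- function(state, weekday) {
  e <- new.env(parent = emptyenv())
  e$cp <- .compile_ruleset(state$ruleset, weekday, state$config)
  e$cd <- state$config$cooldown_min
  e$phase <- state$phase
  e$cooldown <- state$cooldown
  e$stamps <- state$stamps
  e$absence_seen <- state$absence_seen
  e$last_value <- state$last_value
  e$last_minute <- state$last_minute
  e$day_max <- state$day_max
  e$day_max_day <- state$day_max_day
  e$last_processed <- state$last_processed
  e$alerts <- vector("list", 64L)
  e$n_alerts <- 0L
  e
}

.engine_fold <- function(state, e) {
  state$cooldown <- e$cooldown
  state$stamps <- e$stamps
  state$absence_seen <- e$absence_seen
  state$last_value <- e$last_value
  state$last_minute <- e$last_minute
  state$day_max <- e$day_max
  state$day_max_day <- e$day_max_day
  state$last_processed <- e$last_processed
  state
}

.emit <- function(e, key, now, severity, message, rule_id = key) {
  if (e$phase == "calibration") return(FALSE)
  if (!.gate_ok(e$cooldown[[key]], now, e$cd)) return(FALSE)
  e$cooldown[[key]] <- now
  e$n_alerts <- e$n_alerts + 1L
  if (e$n_alerts > length(e$alerts)) length(e$alerts) <- 2L * length(e$alerts)
  e$alerts[[e$n_alerts]] <- list(now = now, rule_id = rule_id,
                                 severity = severity, message = message)
  TRUE
}

# Process one minute of inputs. `vals` is a numeric vector ordered as
# periodic_sensors() (NA where no reading), `evs` a character vector of
# triggered event sensors (repeats allowed). Meta-rules are evaluated before
# single rules (they have priority and may suppress component alerts).
.minute_step <- function(e, day_abs, m, vals, evs) {
  now <- day_abs + m
  if (now <= e$last_processed) {
    stop("time went backwards: minute ", fmt_hm(m), " already processed")
  }
  e$last_processed <- now
  cp <- e$cp
  mi <- m + 1L

  t_val <- vals[[1L]]
  cur_delta <- NA_real_
  if (!is.na(t_val)) {
    # stored daytime maximum (reset when the window opens on a new day)
    if (m >= cp$daywin[[1L]] && m < cp$daywin[[2L]]) {
      d <- as.integer(day_abs %/% 1440)
      if (is.na(e$day_max_day) || e$day_max_day != d) {
        e$day_max <- -Inf
        e$day_max_day <- d
      }
      if (t_val > e$day_max) e$day_max <- t_val
    }
    if (!is.na(e$last_minute[[1L]]) && e$last_minute[[1L]] == now - 1) {
      cur_delta <- t_val - e$last_value[[1L]]
      for (dl in cp$rise_deltas) {
        if (cur_delta >= dl) e$stamps[[sprintf("rise_%g", dl)]] <- now
      }
    }
  }
  l_val <- vals[[4L]]
  if (!is.na(l_val)) {
    for (th in cp$lowlight_thresholds) {
      if (l_val <= th) e$stamps[[sprintf("lightlow_%g", th)]] <- now
    }
  }

  if (length(evs)) {
    for (s in unique(evs)) {
      e$stamps[[paste0("ev_", s)]] <- now
      um <- cp$unusual_mask[[s]]
      if (!is.null(um) && um[[mi]]) e$stamps[[paste0("unusual_", s)]] <- now
      for (a in cp$absence_by_sensor[[s]]) {
        if (a$mask[[mi]]) {
          for (r in a$ranges) {
            if (m >= r[[1L]] && m < r[[2L]]) {
              e$absence_seen[[sprintf("%s@%d", a$id, r[[1L]])]] <- TRUE
            }
          }
        }
      }
    }
  }

  # meta-rules first: they have priority and may withhold component alerts
  suppressed <- character(0)
  for (mt in cp$metas) {
    t1 <- e$stamps[[mt$k1]]
    t2 <- e$stamps[[mt$k2]]
    if (is.null(t1) || is.null(t2)) next
    if (min(t1, t2) >= now - mt$w && max(t1, t2) == now) {
      if (mt$suppress) suppressed <- c(suppressed, mt$suppress_keys)
      if (.emit(e, mt$id, now, mt$severity,
                sprintf("combined condition %s at %s", mt$id, fmt_hm(m))) &&
          mt$suppress) {
        # stamp the component keys so their own alerts stay quiet this window
        for (k in mt$suppress_keys) e$cooldown[[k]] <- now
      }
    }
  }

  # permanent event-presence rules (gas; fire when explicitly enabled)
  if (length(evs)) {
    for (ev in cp$event) {
      if (ev$sensor %in% evs && !(ev$id %in% suppressed)) {
        .emit(e, ev$id, now, "alert",
              sprintf("%s detected at %s", ev$sensor, fmt_hm(m)))
      }
    }
    for (p in cp$presence) {
      if (p$sensor %in% evs && p$mask[[mi]] && !(p$id %in% suppressed)) {
        .emit(e, p$id, now, "alert",
              sprintf("%s during unusual hours at %s", p$sensor, fmt_hm(m)))
      }
    }
  }

  if (!is.na(t_val)) {
    for (th in cp$th) {
      v <- vals[[th$si]]
      if (!is.na(v) && ((th$lo && v < th$thr) || (!th$lo && v > th$thr))) {
        .emit(e, th$id, now, "alert",
              sprintf("temperature %.1f beyond %s limit %g at %s", v,
                      if (th$lo) "lower" else "upper", th$thr, fmt_hm(m)))
      }
    }
    if (!is.na(cur_delta)) {
      for (dr in cp$delta) {
        if (cur_delta >= dr$delta) {
          .emit(e, dr$id, now, "alert",
                sprintf("temperature rose %.1f degC in one minute at %s",
                        cur_delta, fmt_hm(m)))
        }
      }
    }
    if (is.finite(e$day_max)) {
      for (nr in cp$night) {
        if (nr$mask[[mi]] && t_val >= e$day_max) {
          .emit(e, nr$id, now, "alert",
                sprintf("bedtime temperature %.1f >= daytime maximum %.1f at %s",
                        t_val, e$day_max, fmt_hm(m)))
        }
      }
    }
  }
  if (!is.na(l_val)) {
    for (lr in cp$light) {
      if (lr$mask[[mi]] && ((lr$lo && l_val < lr$thr) || (!lr$lo && l_val > lr$thr))) {
        .emit(e, lr$id, now, "alert",
              sprintf("light level %.1f%% %s %g%% at %s", l_val,
                      if (lr$lo) "below" else "above", lr$thr, fmt_hm(m)))
      }
    }
  }

  # absence rules are decided at the minute their range closes
  for (a in cp$absence) {
    for (r in a$ranges) {
      if (r[[2L]] == m &&
          !isTRUE(e$absence_seen[[sprintf("%s@%d", a$id, r[[1L]])]])) {
        .emit(e, a$id, now, "alert",
              sprintf("no %s during usual hours %s-%s", a$sensor,
                      fmt_hm(r[[1L]]), fmt_hm(r[[2L]])))
      }
    }
  }

  # update last readings
  for (si in seq_along(vals)) {
    if (!is.na(vals[[si]])) {
      e$last_value[[si]] <- vals[[si]]
      e$last_minute[[si]] <- now
    }
  }
  invisible(NULL)
}

# ranges closing at 24:00 are decided at day end (timestamped 23:59)
.day_end <- function(e, day_abs) {
  for (a in e$cp$absence) {
    for (r in a$ranges) {
      if (r[[2L]] == 1440L &&
          !isTRUE(e$absence_seen[[sprintf("%s@%d", a$id, r[[1L]])]])) {
        .emit(e, a$id, day_abs + 1439, "alert",
              sprintf("no %s during usual hours %s-%s", a$sensor,
                      fmt_hm(r[[1L]]), fmt_hm(r[[2L]])))
      }
    }
  }
  invisible(NULL)
}

.collect_alerts <- function(e, date) {
  n <- e$n_alerts
  if (n == 0L) {
    return(tibble::tibble(timestamp = as.POSIXct(character(0), tz = "UTC"),
                          date = as.Date(character(0)), minute = integer(0),
                          rule_id = character(0), severity = character(0),
                          message = character(0)))
  }
  al <- e$alerts[seq_len(n)]
  now <- vapply(al, `[[`, numeric(1), "now")
  mins <- as.integer(now %% 1440)
  dates <- as.Date(now %/% 1440, origin = "1970-01-01")
  tibble::tibble(
    timestamp = as.POSIXct(now * 60, origin = "1970-01-01", tz = "UTC"),
    date = dates,
    minute = mins,
    rule_id = vapply(al, `[[`, character(1), "rule_id"),
    severity = vapply(al, `[[`, character(1), "severity"),
    message = vapply(al, `[[`, character(1), "message"))
}

.iso_weekday <- function(date) as.integer(format(date, "%u"))

#' Advance the engine by one minute of inputs
#'
#' Evaluates meta-rules (which have priority and may withhold their
#' component rules' alerts), then single rules, applies the cooldown gate
#' and returns any alerts. In the `"calibration"` phase the state is updated
#' but the alert list is always empty. Successive calls must move forward in
#' time. Absence ranges closing at 24:00 are decided by [run_day()], which
#' knows when the day is complete; `engine_step()` handles those closing at
#' any earlier minute.
#'
#' @param state Engine state.
#' @param date Date of the inputs.
#' @param minute Minute of day, 0-1439.
#' @param readings Named numeric vector of periodic readings for this minute
#'   (names from [periodic_sensors()]); may be `NULL`.
#' @param events Character vector of triggered event sensors (repeats
#'   allowed); may be `NULL`.
#' @return `list(state = updated state, alerts = tibble)`.
#' @export
engine_step <- function(state, date, minute, readings = NULL, events = NULL) {
  stopifnot(inherits(state, "engine_state"), inherits(date, "Date"))
  minute <- as.integer(minute)
  stopifnot(minute >= 0L, minute < 1440L)
  if (is.na(state$current_date) || date > state$current_date) {
    state$absence_seen <- list()     # midnight reset of activity flags
    state$current_date <- date
  } else if (date < state$current_date) {
    stop("time went backwards: date precedes the engine's current day")
  }
  e <- .engine_env(state, .iso_weekday(date))
  vals <- stats::setNames(rep(NA_real_, 5L), periodic_sensors())
  if (!is.null(readings)) vals[names(readings)] <- readings
  .minute_step(e, .day_abs(date), minute, vals,
               if (is.null(events)) character(0) else events)
  state <- .engine_fold(state, e)
  list(state = state, alerts = .collect_alerts(e, date))
}

#' Run the engine over one full day of inputs
#'
#' Folds the minute evaluation over the whole day in timestamp order,
#' performs the end-of-day absence evaluations (ranges closing at 24:00) and
#' the midnight reset of activity flags, and returns the day's alerts.
#' Minutes absent from the trace are skipped; consecutive-minute rise rules
#' are inert across such gaps.
#'
#' @param state Engine state whose last processed day (if any) precedes
#'   `trace$date`.
#' @param trace A [daily_trace()].
#' @return `list(state = updated state, alerts = tibble)` with one alert row
#'   per emitted message (columns `timestamp`, `date`, `minute`, `rule_id`,
#'   `severity`, `message`).
#' @export
run_day <- function(state, trace) {
  stopifnot(inherits(state, "engine_state"), inherits(trace, "daily_trace"))
  if (!is.na(state$current_date) && trace$date <= state$current_date) {
    stop("out-of-order trace: ", format(trace$date), " does not follow ",
         format(state$current_date))
  }
  state$absence_seen <- list()
  state$current_date <- trace$date
  day_abs <- .day_abs(trace$date)
  e <- .engine_env(state, .iso_weekday(trace$date))

  # dense per-minute layout
  r <- trace$readings
  mat <- matrix(NA_real_, nrow = 1440L, ncol = 5L)
  if (nrow(r)) {
    mat[cbind(r$minute + 1L, match(r$sensor, periodic_sensors()))] <- r$value
  }
  ev <- trace$events
  ev_by_min <- if (nrow(ev)) {
    split(ev$sensor, factor(ev$minute, levels = 0:1439))
  } else NULL

  # minutes at which an absence range closes must be visited even if the
  # trace has no inputs there -- the alert is about what did NOT happen
  closing <- rep(FALSE, 1440L)
  for (a in e$cp$absence) {
    for (rg in a$ranges) if (rg[[2L]] < 1440L) closing[rg[[2L]] + 1L] <- TRUE
  }

  for (m in 0:1439) {
    vals <- mat[m + 1L, ]
    evs <- if (is.null(ev_by_min)) character(0) else ev_by_min[[m + 1L]]
    if (length(evs) == 0L && all(is.na(vals)) && !closing[m + 1L]) next
    .minute_step(e, day_abs, m, vals, evs)
  }
  .day_end(e, day_abs)
  state <- .engine_fold(state, e)
  list(state = state, alerts = .collect_alerts(e, trace$date))
}

#' Run the engine over consecutive daily traces
#'
#' @param state Engine state.
#' @param traces List of [daily_trace()] objects with increasing dates.
#' @return `list(state, alerts)` with all days' alerts row-bound.
#' @export
run_traces <- function(state, traces) {
  out <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    res <- run_day(state, traces[[i]])
    state <- res$state
    out[[i]] <- res$alerts
  }
  list(state = state, alerts = dplyr::bind_rows(out))
}
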