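RULE_KINDS <- c("threshold_low", "threshold_high", "delta_rise", "night_vs_day",
                "presence_in_range", "absence_in_range", "light_low_in_range",
                "light_high_in_range", "event_presence")

#' Construct a monitoring rule
#'
#' A rule watches one sensor and fires when its condition holds; fired rules
#' become alert messages (subject to the cooldown gate and meta-rule
#' suppression). Kinds:
#'
#' * `threshold_low` / `threshold_high`: periodic value strictly below/above
#'   `threshold`, checked every minute.
#' * `delta_rise`: rise of at least `delta` between two consecutive minute
#'   readings of the same channel.
#' * `night_vs_day`: during the rule's `ranges` (bedtime), the current
#'   temperature is greater than or equal to the highest temperature stored
#'   over the daytime window `day_window` (default 09:00-16:00).
#' * `presence_in_range`: an event occurs inside an unusual time range.
#' * `absence_in_range`: no event occurred inside a usual time range; decided
#'   once, at the minute the range closes.
#' * `light_low_in_range` / `light_high_in_range`: light level strictly
#'   below/above `threshold` (%) inside the range.
#' * `event_presence`: an event of the sensor occurred (any time of day).
#'
#' Permanent rules (gas presence, fire presence) are never modified by the
#' learning life-cycle; `event_presence` rules must be permanent.
#'
#' @param rule_id Unique identifier; also the cooldown key.
#' @param kind One of the kinds above.
#' @param sensor Sensor the rule watches.
#' @param mutability `"permanent"` or `"modifiable"`.
#' @param threshold Numeric threshold (degC or % light) for threshold/light kinds.
#' @param delta Minimum rise in degC between consecutive minutes (`delta_rise`).
#' @param ranges List of [make_time_range()] ranges for range kinds.
#' @param day_window Daytime window over which the running maximum feeding
#'   `night_vs_day` is accumulated.
#' @param weekdays Integer vector of ISO weekdays (1 = Monday .. 7 = Sunday)
#'   the rule applies to; `NULL` means every day. Weekday-specific rules are
#'   produced by [stable_review()].
#' @param enabled Logical; disabled rules are kept in the ruleset but never
#'   fire (used for the plain fire-presence rule, which by default is
#'   superseded by the fire + temperature-rise meta-rule).
#' @return An object of class `hs_rule`.
#' @export
rule <- function(rule_id, kind, sensor, mutability = "modifiable",
                 threshold = NULL, delta = NULL, ranges = list(),
                 day_window = make_time_range(540, 960),
                 weekdays = NULL, enabled = TRUE) {
  kind <- match.arg(kind, RULE_KINDS)
  mutability <- match.arg(mutability, c("permanent", "modifiable"))
  if (!sensor %in% sensor_kinds()) stop("unknown sensor: ", sensor)
  if (kind == "event_presence") {
    if (!sensor %in% event_sensors()) stop("event_presence rules need an event sensor")
    if (mutability != "permanent") stop("event_presence rules are permanent")
  }
  range_kinds <- c("presence_in_range", "absence_in_range",
                   "light_low_in_range", "light_high_in_range", "night_vs_day")
  if (kind %in% range_kinds && length(ranges) == 0L) {
    stop("rule kind '", kind, "' requires at least one time range")
  }
  if (!is.null(threshold)) threshold <- as.numeric(threshold)
  if (!is.null(delta)) delta <- as.numeric(delta)
  ranges <- lapply(ranges, function(r) make_time_range(r[[1L]], r[[2L]]))
  if (!is.null(weekdays)) {
    weekdays <- as.integer(weekdays)
    stopifnot(all(weekdays %in% 1:7))
  }
  structure(list(rule_id = rule_id, kind = kind, sensor = sensor,
                 mutability = mutability, threshold = threshold, delta = delta,
                 ranges = ranges, day_window = day_window,
                 weekdays = weekdays, enabled = isTRUE(enabled)),
            class = "hs_rule")
}

#' @export
format.hs_rule <- function(x, ...) {
  rng <- if (length(x$ranges)) paste(vapply(x$ranges, format, character(1)),
                                     collapse = " ")
         else ""
  par <- c(if (!is.null(x$threshold)) sprintf("threshold=%g", x$threshold),
           if (!is.null(x$delta)) sprintf("delta=%g", x$delta),
           if (nzchar(rng)) rng,
           if (!is.null(x$weekdays)) paste0("weekdays=", paste(x$weekdays, collapse = ",")),
           if (!x$enabled) "disabled")
  sprintf("%-28s %-19s %-12s %-10s %s", x$rule_id, x$kind, x$sensor,
          x$mutability, paste(par, collapse = " "))
}

#' @export
print.hs_rule <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Construct a coincidence meta-rule
#'
#' A meta-rule watches two component conditions and fires once, when the
#' later of the two occurs, provided both fell within the trailing
#' coincidence window. Meta-rules take priority over single rules: when
#' `suppress_components` is set, the component rules' own alerts are withheld
#' for the window (a single notification is sent).
#'
#' Component specifications are lists with a `type` field:
#' * `list(type = "event", sensor = )`: any event of that sensor.
#' * `list(type = "event_in_unusual", sensor = )`: an event of that sensor
#'   inside one of the sensor's `presence_in_range` (unusual) ranges,
#'   `suppresses` naming the presence rules it silences.
#' * `list(type = "temp_rise", delta = )`: a consecutive-minute temperature
#'   rise of at least `delta` degC.
#' * `list(type = "light_low_state", threshold = )`: the light reading is at
#'   or below `threshold` %.
#'
#' @param meta_id Identifier; also the cooldown key for the combined alert.
#' @param components List of exactly two component specifications.
#' @param coincidence_window_min Window length in minutes (default 10) within
#'   which the two components must co-occur.
#' @param severity `"alert"` or `"emergency"`. Only the fire +
#'   temperature-rise meta-rule sends an emergency.
#' @param suppress_components Withhold the component rules' individual alerts
#'   when the meta-rule covers them.
#' @param mutability `"permanent"` or `"modifiable"`.
#' @return An object of class `hs_meta_rule`.
#' @export
meta_rule <- function(meta_id, components, coincidence_window_min = 10L,
                      severity = c("alert", "emergency"),
                      suppress_components = TRUE,
                      mutability = "modifiable") {
  severity <- match.arg(severity)
  mutability <- match.arg(mutability, c("permanent", "modifiable"))
  if (length(components) != 2L) stop("a meta-rule has exactly two components")
  components <- lapply(components, function(cp) {
    if (!cp$type %in% c("event", "event_in_unusual", "temp_rise", "light_low_state")) {
      stop("unknown meta-rule component type: ", cp$type)
    }
    if (!is.null(cp$delta)) cp$delta <- as.numeric(cp$delta)
    if (!is.null(cp$threshold)) cp$threshold <- as.numeric(cp$threshold)
    cp
  })
  structure(list(meta_id = meta_id, components = components,
                 coincidence_window_min = as.integer(coincidence_window_min),
                 severity = severity,
                 suppress_components = isTRUE(suppress_components),
                 mutability = mutability),
            class = "hs_meta_rule")
}

#' @export
format.hs_meta_rule <- function(x, ...) {
  comp <- vapply(x$components, function(cp) {
    switch(cp$type,
           event = paste0("event:", cp$sensor),
           event_in_unusual = paste0("unusual:", cp$sensor),
           temp_rise = sprintf("temp_rise>=%g", cp$delta),
           light_low_state = sprintf("light<=%g%%", cp$threshold))
  }, character(1))
  sprintf("%-28s meta(%s + %s, %d min) %s%s", x$meta_id, comp[1], comp[2],
          x$coincidence_window_min, x$severity,
          if (x$suppress_components) " [suppresses components]" else "")
}

#' @export
print.hs_meta_rule <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' The default rule catalogue
#'
#' Returns the factory ruleset the system starts from before any behaviour
#' has been learned: temperature floor 15 degC and ceiling 38 degC, a 2 degC
#' consecutive-minute rise rule, bedtime-vs-daytime temperature comparison
#' over 23:00-24:00 and 00:00-07:00 against the 09:00-16:00 daytime maximum,
#' a permanent gas-presence rule, a permanent fire-presence rule (disabled by
#' default: fire alone is prone to false positives, so fire alerts are routed
#' through the fire + temperature-rise meta-rule), four movement range rules
#' (presence 00:00-08:00 and 23:00-24:00; absence 09:00-12:00 and
#' 16:00-18:00), two TV-remote range rules (presence 00:00-08:00 and
#' 22:00-24:00), evening light floor 20 % over 18:00-21:00, nighttime light
#' ceiling 1 % over 23:00-24:00 and 00:00-05:00, and three meta-rules
#' (movement + TV at unusual hours, movement in low light at unusual hours,
#' and fire + temperature rise of at least 1 degC, which sends an emergency).
#'
#' @param fire_plain_rule_enabled Enable the literal stand-alone
#'   fire-presence rule in addition to the meta-rule.
#' @param coincidence_window_min Coincidence window for the meta-rules.
#' @return List of [rule()] and [meta_rule()] objects.
#' @export
default_ruleset <- function(fire_plain_rule_enabled = FALSE,
                            coincidence_window_min = 10L) {
  rng <- function(a, b) list(make_time_range(parse_hm(a), parse_hm(b)))
  list(
    rule("temp_low", "threshold_low", "temperature", threshold = 15),
    rule("temp_high", "threshold_high", "temperature", threshold = 38),
    rule("temp_rise", "delta_rise", "temperature", delta = 2),
    rule("temp_night_early", "night_vs_day", "temperature",
         ranges = rng("00:00", "07:00")),
    rule("temp_night_late", "night_vs_day", "temperature",
         ranges = rng("23:00", "24:00")),
    rule("gas", "event_presence", "gas_presence", mutability = "permanent"),
    rule("fire", "event_presence", "fire", mutability = "permanent",
         enabled = fire_plain_rule_enabled),
    rule("motion_presence_00h", "presence_in_range", "motion",
         ranges = rng("00:00", "08:00")),
    rule("motion_presence_23h", "presence_in_range", "motion",
         ranges = rng("23:00", "24:00")),
    rule("motion_absence_09h", "absence_in_range", "motion",
         ranges = rng("09:00", "12:00")),
    rule("motion_absence_16h", "absence_in_range", "motion",
         ranges = rng("16:00", "18:00")),
    rule("tv_presence_00h", "presence_in_range", "tv_remote",
         ranges = rng("00:00", "08:00")),
    rule("tv_presence_22h", "presence_in_range", "tv_remote",
         ranges = rng("22:00", "24:00")),
    rule("light_low_evening", "light_low_in_range", "light", threshold = 20,
         ranges = rng("18:00", "21:00")),
    rule("light_high_night", "light_high_in_range", "light", threshold = 1,
         ranges = c(rng("23:00", "24:00"), rng("00:00", "05:00"))),
    meta_rule("meta_motion_tv",
              list(list(type = "event_in_unusual", sensor = "motion"),
                   list(type = "event_in_unusual", sensor = "tv_remote")),
              coincidence_window_min = coincidence_window_min,
              severity = "alert", suppress_components = TRUE),
    meta_rule("meta_motion_lowlight",
              list(list(type = "event_in_unusual", sensor = "motion"),
                   list(type = "light_low_state", threshold = 1)),
              coincidence_window_min = coincidence_window_min,
              severity = "alert", suppress_components = TRUE),
    meta_rule("meta_fire_temp",
              list(list(type = "event", sensor = "fire"),
                   list(type = "temp_rise", delta = 1)),
              coincidence_window_min = coincidence_window_min,
              severity = "emergency", suppress_components = TRUE,
              mutability = "permanent")
  )
}

#' Split a ruleset into single rules and meta-rules
#'
#' @param ruleset List of rules and meta-rules.
#' @return List of `hs_rule` (resp. `hs_meta_rule`) objects.
#' @export
ruleset_rules <- function(ruleset) {
  Filter(function(x) inherits(x, "hs_rule"), ruleset)
}

#' @rdname ruleset_rules
#' @export
ruleset_metas <- function(ruleset) {
  Filter(function(x) inherits(x, "hs_meta_rule"), ruleset)
}

#' @export
print.hs_ruleset <- function(x, ...) {
  for (r in x) cat(format(r), "\n")
  invisible(x)
}
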