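#' Learning life-cycle configuration
#'
#' The system learns in three phases: a calibration period (default 14
#' days) in which behaviour is profiled and no alerts are sent, a
#' readjustment period (default another 14 days) with alerting enabled
#' while rules keep adapting daily, and a stable period in which rules only
#' change after a repeated alert pattern is reviewed.
#'
#' @param calibration_days,readjustment_days Phase lengths in days.
#' @param bin_width Profile bin width in minutes (default 60: the rule
#'   vocabulary is whole hours).
#' @param usual_fraction An hour bin counts as "usual" when activity was
#'   seen there on at least this fraction of observed days (default 0.5).
#' @param repeat_threshold Number of same-pattern alerts within the review
#'   window that triggers a rule modification in the stable phase.
#' @param review_window_days Trailing window for [stable_review()].
#' @return A list of class `learning_config`.
#' @export
learning_config <- function(calibration_days = 14L, readjustment_days = 14L,
                            bin_width = 60L, usual_fraction = 0.5,
                            repeat_threshold = 3L, review_window_days = 28L) {
  stopifnot(calibration_days >= 1L, readjustment_days >= 0L,
            bin_width >= 1L, 1440L %% bin_width == 0L,
            usual_fraction > 0, usual_fraction <= 1,
            repeat_threshold >= 1L, review_window_days >= 1L)
  structure(list(calibration_days = as.integer(calibration_days),
                 readjustment_days = as.integer(readjustment_days),
                 bin_width = as.integer(bin_width),
                 usual_fraction = usual_fraction,
                 repeat_threshold = as.integer(repeat_threshold),
                 review_window_days = as.integer(review_window_days)),
            class = "learning_config")
}

#' Create an empty behaviour profile
#'
#' A profile counts, per time-of-day bin, on how many observed days the
#' sensor produced at least one qualifying event in that bin, both overall
#' and stratified by ISO weekday. It is the substrate from which
#' usual/unusual time-range rules are derived.
#'
#' @param sensor Sensor name (typically `"motion"` or `"tv_remote"`).
#' @param bin_width Bin width in minutes; must divide 1440.
#' @return An object of class `behavior_profile`.
#' @export
new_profile <- function(sensor, bin_width = 60L) {
  stopifnot(sensor %in% sensor_kinds(), 1440L %% bin_width == 0L)
  nb <- 1440L %/% bin_width
  structure(list(sensor = sensor, bin_width = as.integer(bin_width),
                 days_observed = 0L, counts = integer(nb),
                 per_weekday_counts = matrix(0L, nrow = 7L, ncol = nb,
                                             dimnames = list(weekday = 1:7, NULL)),
                 dates = character(0)),
            class = "behavior_profile")
}

#' @export
print.behavior_profile <- function(x, ...) {
  cat(sprintf("<behavior_profile> %s: %d days, %d-min bins, active bins: %s\n",
              x$sensor, x$days_observed, x$bin_width,
              paste(which(x$counts > 0L) - 1L, collapse = " ")))
  invisible(x)
}

#' Binarise one day of activity into time bins
#'
#' For event sensors, a bin is active when at least one event fell inside
#' it. For periodic sensors a qualifying threshold must be supplied: a bin
#' is active when any reading in it exceeds `threshold`.
#'
#' @param trace A [daily_trace()].
#' @param sensor Sensor to binarise.
#' @param bin_width Bin width in minutes.
#' @param threshold Qualifying threshold for periodic sensors.
#' @return Logical vector of length `1440 / bin_width`.
#' @export
binarize_day <- function(trace, sensor, bin_width = 60L, threshold = NULL) {
  stopifnot(inherits(trace, "daily_trace"), 1440L %% bin_width == 0L)
  nb <- 1440L %/% bin_width
  if (sensor %in% event_sensors()) {
    mins <- trace$events$minute[trace$events$sensor == sensor]
  } else if (sensor %in% periodic_sensors()) {
    if (is.null(threshold)) {
      stop("binarize_day() on a periodic sensor requires `threshold`")
    }
    idx <- trace$readings$sensor == sensor & trace$readings$value > threshold
    mins <- trace$readings$minute[idx]
  } else {
    stop("unknown sensor: ", sensor)
  }
  out <- rep(FALSE, nb)
  out[unique(mins %/% bin_width) + 1L] <- TRUE
  out
}

#' Accumulate one day of observations into a profile
#'
#' @param profile A [new_profile()].
#' @param trace A [daily_trace()] whose date has not been accumulated yet.
#' @param threshold Passed to [binarize_day()] for periodic sensors.
#' @return Updated profile.
#' @export
accumulate_profile <- function(profile, trace, threshold = NULL) {
  stopifnot(inherits(profile, "behavior_profile"))
  key <- format(trace$date)
  if (key %in% profile$dates) stop("date ", key, " already accumulated")
  act <- binarize_day(trace, profile$sensor, profile$bin_width, threshold)
  profile$days_observed <- profile$days_observed + 1L
  profile$counts <- profile$counts + as.integer(act)
  wd <- .iso_weekday(trace$date)
  profile$per_weekday_counts[wd, ] <- profile$per_weekday_counts[wd, ] + as.integer(act)
  profile$dates <- c(profile$dates, key)
  profile
}

# maximal runs of TRUE in a logical vector -> list of time ranges
.runs_to_ranges <- function(flags, bin_width) {
  if (!any(flags)) return(list())
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in seq_along(r$values)) {
    if (r$values[i]) {
      out[[length(out) + 1L]] <-
        make_time_range((starts[i] - 1L) * bin_width, ends[i] * bin_width)
    }
  }
  out
}

#' Derive usual/unusual time-range rules from a behaviour profile
#'
#' Bins active on at least `usual_fraction` of the observed days are
#' "usual" hours; the rest are "unusual". Maximal runs of usual bins become
#' absence rules (alert when no activity where it should occur) and maximal
#' runs of unusual bins become presence rules (alert on activity where none
#' should occur). For the TV remote only presence rules are built: not
#' watching TV is unremarkable.
#'
#' @param profile A [new_profile()] with at least one day observed.
#' @param cfg A [learning_config()].
#' @return List of [rule()] objects, ranges normalised.
#' @export
derive_range_rules <- function(profile, cfg = learning_config()) {
  stopifnot(inherits(profile, "behavior_profile"))
  if (profile$days_observed < 1L) stop("profile has no observed days")
  usual <- profile$counts / profile$days_observed >= cfg$usual_fraction
  bw <- profile$bin_width
  s <- profile$sensor
  mk <- function(kind, rng) {
    tag <- if (kind == "presence_in_range") "presence" else "absence"
    prefix <- if (s == "tv_remote") "tv" else s
    rule(sprintf("%s_%s_%02dh", prefix, tag, rng[[1L]] %/% 60L),
         kind, s, ranges = list(rng))
  }
  out <- lapply(.runs_to_ranges(!usual, bw), function(rng) mk("presence_in_range", rng))
  if (s != "tv_remote") {
    out <- c(out, lapply(.runs_to_ranges(usual, bw),
                         function(rng) mk("absence_in_range", rng)))
  }
  out
}

#' Reconcile an existing ruleset with freshly derived range rules
#'
#' The profile is cumulative, so "expanding or decreasing the hour ranges"
#' is realised as re-derivation: for every sensor/kind combination present
#' in `derived`, the modifiable rules of that combination are replaced by
#' the derived ones (rules no longer supported by the profile disappear).
#' Permanent rules pass through untouched; a derived rule that collides
#' with a permanent rule's id is an error.
#'
#' @param old Current ruleset (rules + meta-rules).
#' @param derived List of derived [rule()]s, e.g. from
#'   [derive_range_rules()].
#' @param cfg A [learning_config()] (reserved for future strategies).
#' @return Updated ruleset.
#' @export
reconcile_rules <- function(old, derived, cfg = learning_config()) {
  if (!length(derived)) return(old)
  perm_ids <- vapply(Filter(function(x) inherits(x, "hs_rule") &&
                              x$mutability == "permanent", old),
                     `[[`, character(1), "rule_id")
  d_ids <- vapply(derived, `[[`, character(1), "rule_id")
  if (any(d_ids %in% perm_ids)) {
    stop("cannot modify permanent rule(s): ",
         paste(intersect(d_ids, perm_ids), collapse = ", "))
  }
  combos <- unique(vapply(derived, function(r) paste(r$sensor, r$kind), character(1)))
  keep <- Filter(function(x) {
    !inherits(x, "hs_rule") ||
      x$mutability == "permanent" ||
      !(paste(x$sensor, x$kind) %in% combos)
  }, old)
  derived <- lapply(derived, function(r) { r$ranges <- normalize_ranges(r$ranges); r })
  c(keep, derived)
}

#' Phase of the life-cycle for a given day index
#'
#' @param day_index Zero-based day counter.
#' @param cfg A [learning_config()].
#' @return `"calibration"`, `"readjustment"` or `"stable"`.
#' @export
lifecycle_phase <- function(day_index, cfg = learning_config()) {
  if (day_index < cfg$calibration_days) "calibration"
  else if (day_index < cfg$calibration_days + cfg$readjustment_days) "readjustment"
  else "stable"
}

#' Process one day through the adaptive life-cycle
#'
#' Runs the engine over the trace under the phase dictated by the state's
#' day counter, then -- in the calibration and readjustment phases --
#' accumulates the day into the behaviour profiles, re-derives the range
#' rules and reconciles them into the ruleset. In the stable phase the
#' ruleset is left alone (changes there go through [stable_review()]).
#' Calibration days produce no alerts.
#'
#' @param state Engine state.
#' @param profiles Named list of [new_profile()]s (by sensor); missing
#'   motion / TV profiles are created.
#' @param trace The day's [daily_trace()].
#' @param cfg A [learning_config()].
#' @return `list(state, profiles, alerts)`.
#' @export
advance_day <- function(state, profiles = NULL, trace, cfg = learning_config()) {
  stopifnot(inherits(state, "engine_state"), inherits(trace, "daily_trace"))
  if (is.null(profiles)) profiles <- list()
  for (s in c("motion", "tv_remote")) {
    if (is.null(profiles[[s]])) profiles[[s]] <- new_profile(s, cfg$bin_width)
  }
  state$phase <- lifecycle_phase(state$day_index, cfg)
  res <- run_day(state, trace)
  state <- res$state
  if (state$phase %in% c("calibration", "readjustment")) {
    derived <- list()
    for (s in names(profiles)) {
      profiles[[s]] <- accumulate_profile(profiles[[s]], trace)
      derived <- c(derived, derive_range_rules(profiles[[s]], cfg))
    }
    state$ruleset <- reconcile_rules(state$ruleset, derived, cfg)
  }
  state$day_index <- state$day_index + 1L
  list(state = state, profiles = profiles, alerts = res$alerts)
}

#' Calibrate a fresh engine on a series of daily traces
#'
#' Convenience wrapper folding [advance_day()] over consecutive traces,
#' starting from a fresh state with the default ruleset.
#'
#' @param traces List of consecutive [daily_trace()]s.
#' @param cfg A [learning_config()].
#' @param config An [engine_config()].
#' @return `list(state, profiles, alerts)`; `alerts` covers the whole
#'   period (empty rows for calibration days).
#' @export
calibrate_engine <- function(traces, cfg = learning_config(),
                             config = engine_config()) {
  state <- new_engine_state(config = config, phase = "calibration")
  profiles <- NULL
  alerts <- list()
  for (tr in traces) {
    res <- advance_day(state, profiles, tr, cfg)
    state <- res$state
    profiles <- res$profiles
    alerts[[length(alerts) + 1L]] <- res$alerts
  }
  list(state = state, profiles = profiles, alerts = dplyr::bind_rows(alerts))
}

#' Annotate an alert log with weekday and time-of-day bin
#'
#' @param alerts Alert tibble as returned by [run_day()].
#' @param bin_width Bin width in minutes.
#' @return The tibble with `weekday` (ISO, 1 = Monday) and `bin` (0-based
#'   time-of-day bin) columns added.
#' @export
annotate_alerts <- function(alerts, bin_width = 60L) {
  alerts$weekday <- .iso_weekday(alerts$date)
  alerts$bin <- alerts$minute %/% as.integer(bin_width)
  alerts
}

#' Review repeated alert patterns in the stable phase
#'
#' Within the trailing review window, alerts are grouped by rule and
#' time-of-day bin, both across all days and stratified by weekday. A group
#' reaching `repeat_threshold` occurrences means the "unusual" behaviour is
#' in fact this resident's routine, so the offending rule range is removed
#' or shrunk: for an all-days pattern the rule's range loses the offending
#' hours (an absence rule loses the range that raised the alert); for a
#' pattern confined to one weekday the rule is split, leaving the original
#' range on the other weekdays and materialising a weekday-specific rule
#' with the offending part removed. Permanent rules are never modified.
#'
#' @param log Alert tibble (e.g. accumulated from [run_day()]).
#' @param ruleset Current ruleset.
#' @param cfg A [learning_config()].
#' @return `list(ruleset = updated ruleset, report = tibble)` where the
#'   report has one row per modification (`rule_id`, `scope`, `weekday`,
#'   `bin`, `n_alerts`, `action`).
#' @export
stable_review <- function(log, ruleset, cfg = learning_config()) {
  report <- tibble::tibble(rule_id = character(0), scope = character(0),
                           weekday = integer(0), bin = integer(0),
                           n_alerts = integer(0), action = character(0))
  if (!nrow(log)) return(list(ruleset = ruleset, report = report))
  log <- annotate_alerts(log, cfg$bin_width)
  cutoff <- max(log$date) - cfg$review_window_days + 1L
  log <- log[log$date >= cutoff, ]
  if (!nrow(log)) return(list(ruleset = ruleset, report = report))

  find_idx <- function(id) {
    ids <- vapply(ruleset, function(x) {
      if (inherits(x, "hs_rule")) x$rule_id else x$meta_id
    }, character(1))
    match(id, ids)
  }

  # For each (rule, time-bin) pattern decide its scope: when one weekday
  # accounts for the repeats and the remaining alerts alone would not cross
  # the threshold, the routine is weekday-specific; otherwise, if the total
  # crosses, it holds across days.
  tot <- dplyr::count(log, rule_id, bin, name = "n_total")
  wd_groups <- dplyr::count(log, rule_id, weekday, bin, name = "n")
  hot_all <- tot[0, ]
  hot_wd <- wd_groups[0, ]
  for (i in seq_len(nrow(tot))) {
    w <- wd_groups[wd_groups$rule_id == tot$rule_id[i] &
                     wd_groups$bin == tot$bin[i], ]
    j <- which.max(w$n)
    if (w$n[j] >= cfg$repeat_threshold &&
        (tot$n_total[i] - w$n[j]) < cfg$repeat_threshold) {
      hot_wd <- dplyr::bind_rows(hot_wd, w[j, ])
    } else if (tot$n_total[i] >= cfg$repeat_threshold) {
      hot_all <- dplyr::bind_rows(hot_all, tot[i, ])
    }
  }

  shrink <- function(r, bin, alerts_minute) {
    bw <- cfg$bin_width
    if (r$kind == "absence_in_range") {
      # the alert fires at the minute the range closes (23:59 for 24:00);
      # drop the range(s) that raised the repeated alerts
      Filter(function(rg) {
        closes_at <- if (rg[[2L]] == 1440L) 1439L else rg[[2L]]
        !any(alerts_minute == closes_at)
      }, r$ranges)
    } else {
      drop <- make_time_range(bin * bw, (bin + 1L) * bw)
      out <- list()
      for (rg in r$ranges) {
        if (rg[[2L]] <= drop[[1L]] || rg[[1L]] >= drop[[2L]]) {
          out[[length(out) + 1L]] <- rg
        } else {
          if (rg[[1L]] < drop[[1L]]) out[[length(out) + 1L]] <- make_time_range(rg[[1L]], drop[[1L]])
          if (rg[[2L]] > drop[[2L]]) out[[length(out) + 1L]] <- make_time_range(drop[[2L]], rg[[2L]])
        }
      }
      out
    }
  }

  apply_mod <- function(rule_id, bin, weekday = NA_integer_) {
    idx <- find_idx(rule_id)
    if (is.na(idx)) return(invisible(NULL))
    r <- ruleset[[idx]]
    if (!inherits(r, "hs_rule") || r$mutability == "permanent") return(invisible(NULL))
    mins <- log$minute[log$rule_id == rule_id & log$bin == bin]
    new_ranges <- shrink(r, bin, mins)
    if (is.na(weekday)) {
      if (length(new_ranges)) {
        r$ranges <- normalize_ranges(new_ranges)
        ruleset[[idx]] <<- r
        action <- "range shrunk"
      } else {
        ruleset[[idx]] <<- NULL
        action <- "rule removed"
      }
      scope <- "all_days"
    } else {
      r_other <- r
      r_other$weekdays <- setdiff(r$weekdays %||% 1:7, weekday)
      ruleset[[idx]] <<- r_other
      if (length(new_ranges)) {
        r_wd <- r
        r_wd$rule_id <- sprintf("%s_wd%d", r$rule_id, weekday)
        r_wd$weekdays <- weekday
        r_wd$ranges <- normalize_ranges(new_ranges)
        ruleset[[length(ruleset) + 1L]] <<- r_wd
        action <- sprintf("weekday %d variant with shrunk range", weekday)
      } else {
        action <- sprintf("rule disabled on weekday %d", weekday)
      }
      scope <- "weekday"
    }
    report <<- dplyr::bind_rows(report, tibble::tibble(
      rule_id = rule_id, scope = scope, weekday = weekday, bin = bin,
      n_alerts = length(mins), action = action))
    invisible(NULL)
  }

  for (i in seq_len(nrow(hot_all))) apply_mod(hot_all$rule_id[i], hot_all$bin[i])
  for (i in seq_len(nrow(hot_wd))) {
    apply_mod(hot_wd$rule_id[i], hot_wd$bin[i], hot_wd$weekday[i])
  }
  list(ruleset = ruleset, report = report)
}
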