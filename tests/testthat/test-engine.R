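rd <- function(minute, value, sensor = "temperature") {
  list(minute = minute, sensor = sensor, value = value)
}

test_that("threshold rules use strict comparisons and check the sensor", {
  lo <- rule("temp_low", "threshold_low", "temperature", threshold = 15)
  hi <- rule("temp_high", "threshold_high", "temperature", threshold = 38)
  expect_true(eval_threshold(lo, rd(600, 14.9)))
  expect_false(eval_threshold(lo, rd(600, 15.0)))   # boundary never fires
  expect_true(eval_threshold(hi, rd(600, 38.5)))
  expect_false(eval_threshold(hi, rd(600, 38.0)))
  expect_error(eval_threshold(lo, rd(600, 50, sensor = "light")), "mismatch")
})

test_that("delta rules compare consecutive minutes only", {
  r2 <- rule("temp_rise", "delta_rise", "temperature", delta = 2)
  r1 <- rule("rise1", "delta_rise", "temperature", delta = 1)
  expect_true(eval_delta(r2, rd(100, 20.0), rd(101, 22.1)))
  expect_false(eval_delta(r2, rd(100, 20.0), rd(101, 21.9)))
  expect_true(eval_delta(r1, rd(100, 20.0), rd(101, 21.0)))  # feeds the fire meta-rule
  expect_error(eval_delta(r2, rd(100, 20.0), rd(102, 23.0)), "consecutive")
})

test_that("the daytime maximum is monotone within the window and ignores the rest", {
  st <- new_engine_state()
  st$current_date <- as.Date("2021-03-03")
  st <- update_day_max(st, rd(840, 21.5))
  expect_identical(st$day_max, 21.5)
  st <- update_day_max(st, rd(841, 21.8))   # 14:01, new maximum
  expect_identical(st$day_max, 21.8)
  st <- update_day_max(st, rd(900, 20.0))   # lower reading: maximum keeps
  expect_identical(st$day_max, 21.8)
  st <- update_day_max(st, rd(1020, 30.0))  # 17:00 outside 09:00-16:00
  expect_identical(st$day_max, 21.8)
  # a new day's window resets the stored maximum
  st <- update_day_max(st, rd(540, 19.0), date = as.Date("2021-03-04"))
  expect_identical(st$day_max, 19.0)
})

test_that("bedtime temperature fires at or above the stored daytime maximum", {
  early <- rule("temp_night_early", "night_vs_day", "temperature",
                ranges = list(make_time_range(0, 420)))
  late <- rule("temp_night_late", "night_vs_day", "temperature",
               ranges = list(make_time_range(1380, 1440)))
  st <- new_engine_state()
  st$day_max <- 21.8
  expect_true(eval_night_vs_day(early, st, rd(parse_hm("02:01"), 21.9)))
  expect_true(eval_night_vs_day(early, st, rd(parse_hm("02:01"), 21.8)))  # >= semantics
  st$day_max <- 23.8
  expect_true(eval_night_vs_day(late, st, rd(parse_hm("23:17"), 23.9)))
  expect_false(eval_night_vs_day(late, st, rd(parse_hm("23:17"), 23.0)))
  expect_false(eval_night_vs_day(late, st, rd(840, 30)))  # outside bedtime
  st$day_max <- NA_real_                                  # no stored maximum: inert
  expect_false(eval_night_vs_day(early, st, rd(121, 30)))
})

test_that("presence rules match sensor and unusual ranges", {
  mp <- rule("mp", "presence_in_range", "motion",
             ranges = list(make_time_range(0, 480), make_time_range(1380, 1440)))
  tv <- rule("tv", "presence_in_range", "tv_remote",
             ranges = list(make_time_range(1320, 1440)))
  expect_true(eval_presence(mp, list(minute = parse_hm("23:30"), sensor = "motion")))
  expect_true(eval_presence(tv, list(minute = parse_hm("22:00"), sensor = "tv_remote")))
  expect_false(eval_presence(mp, list(minute = 720L, sensor = "motion")))
  expect_false(eval_presence(mp, list(minute = 100L, sensor = "tv_remote")))
})

test_that("absence rules are decided exactly when the range closes", {
  ab <- rule("motion_absence_16h", "absence_in_range", "motion",
             ranges = list(make_time_range(960, 1080)))
  st <- new_engine_state()
  expect_true(eval_absence(ab, st, 1080L))    # no activity seen, range closed
  expect_false(eval_absence(ab, st, 1079L))   # still inside: not decidable
  st$absence_seen[["motion_absence_16h@960"]] <- TRUE
  expect_false(eval_absence(ab, st, 1080L))   # activity was seen
})

test_that("cooldown gate reproduces the half-hour-window throttling arithmetic", {
  st <- new_engine_state()
  day <- as.numeric(as.Date("2021-03-16")) * 1440
  g <- cooldown_gate(st, "gas", day + parse_hm("13:56"))
  expect_true(g$emit)                         # first-ever alert passes
  st <- g$state
  # 14:29 is 33 min later but its half-hour window opened at 14:00,
  # only 4 min after the alert: swallowed
  expect_false(cooldown_gate(st, "gas", day + parse_hm("14:29"))$emit)
  expect_true(cooldown_gate(st, "gas", day + parse_hm("14:30"))$emit)
  expect_true(cooldown_gate(st, "gas", day + parse_hm("15:35"))$emit)
  # independent keys do not interact
  expect_true(cooldown_gate(st, "motion_presence_00h", day + parse_hm("13:57"))$emit)
})

test_that("consecutive emitted alerts for one key are >= 30 min apart", {
  set.seed(7)
  for (i in 1:100) {
    st <- new_engine_state()
    times <- sort(sample(0:4319, 60))         # three days of random events
    emitted <- numeric(0)
    for (t in times) {
      g <- cooldown_gate(st, "k", t)
      st <- g$state
      if (g$emit) emitted <- c(emitted, t)
    }
    if (length(emitted) > 1) expect_true(all(diff(emitted) >= 30))
    # and at most one emission per aligned half-hour window
    expect_false(any(duplicated(emitted %/% 30)))
  }
})

test_that("gas events alert in stable phase, never during calibration", {
  d <- as.Date("2021-03-16")
  st <- new_engine_state()
  res <- engine_step(st, d, 800L, events = "gas_presence")
  expect_identical(nrow(res$alerts), 1L)
  expect_identical(res$alerts$rule_id, "gas")
  cal <- new_engine_state(phase = "calibration")
  res2 <- engine_step(cal, d, 800L, events = "gas_presence")
  expect_identical(nrow(res2$alerts), 0L)
  # state still updated during calibration (activity flags etc.)
  res3 <- engine_step(res2$state, d, 801L, events = "motion")
  expect_identical(nrow(res3$alerts), 0L)
})

test_that("fire alone does not alert; fire plus a 1 degC rise is an emergency", {
  d <- as.Date("2021-03-16")
  st <- new_engine_state()
  res <- engine_step(st, d, 1316L, readings = c(temperature = 20), events = "fire")
  expect_identical(nrow(res$alerts), 0L)
  res <- engine_step(res$state, d, 1317L, readings = c(temperature = 21.0))
  expect_identical(res$alerts$rule_id, "meta_fire_temp")
  expect_identical(res$alerts$severity, "emergency")
  # the literal fire rule can be restored by configuration
  st2 <- new_engine_state(config = engine_config(fire_plain_rule_enabled = TRUE))
  res2 <- engine_step(st2, d, 100L, events = "fire")
  expect_identical(res2$alerts$rule_id, "fire")
})

test_that("a fire too far from the rise stays silent", {
  d <- as.Date("2021-03-16")
  st <- new_engine_state()
  res <- engine_step(st, d, parse_hm("13:40"), readings = c(temperature = 20),
                     events = "fire")
  st <- res$state
  # gentle approach, qualifying rise only at 13:52: 12 min after the fire
  v <- 20
  for (m in parse_hm("13:41"):parse_hm("13:51")) {
    res <- engine_step(st, d, m, readings = c(temperature = v))
    st <- res$state
    expect_identical(nrow(res$alerts), 0L)
  }
  res <- engine_step(st, d, parse_hm("13:52"), readings = c(temperature = v + 2.5))
  expect_identical(res$alerts$rule_id, "temp_rise")   # rise alert, no emergency
})

test_that("motion and TV coinciding at unusual hours send a single combined alert", {
  d <- as.Date("2021-03-16")
  st <- new_engine_state()
  res <- engine_step(st, d, parse_hm("02:00"), events = "motion")
  expect_identical(res$alerts$rule_id, "motion_presence_00h")
  res <- engine_step(res$state, d, parse_hm("02:03"), events = "tv_remote")
  # meta-rule covers the TV component: one combined alert, no tv alert
  expect_identical(res$alerts$rule_id, "meta_motion_tv")
})

test_that("engine time cannot go backwards", {
  d <- as.Date("2021-03-16")
  st <- engine_step(new_engine_state(), d, 100L, events = "motion")$state
  expect_error(engine_step(st, d, 100L, events = "motion"), "backwards")
  expect_error(engine_step(st, d, 99L), "backwards")
  expect_error(run_day(st, quiet_day(d)), "out-of-order")
})

test_that("an event-free day raises one alert per absence range, none when active", {
  d <- as.Date("2021-03-16")
  res <- run_day(new_engine_state(), quiet_day(d))
  ab <- res$alerts[grepl("absence", res$alerts$rule_id), ]
  expect_identical(ab$minute, c(720L, 1080L))           # 12:00 and 18:00
  expect_identical(ab$rule_id, c("motion_absence_09h", "motion_absence_16h"))
  # motion every minute: absence alerts vanish
  busy <- quiet_day(d, events = motion_events(0:1439))
  res2 <- run_day(new_engine_state(), busy)
  expect_identical(count_rule(res2$alerts, c("motion_absence_09h",
                                             "motion_absence_16h")), 0L)
})

test_that("calibration silences whole days regardless of content", {
  st <- new_engine_state(phase = "calibration")
  res <- run_day(st, fixture_fire_day())
  expect_identical(nrow(res$alerts), 0L)
  st <- new_engine_state(phase = "calibration")
  res <- run_day(st, quiet_day(as.Date("2021-03-16"),
                               events = motion_events(c(10, 100, 1400))))
  expect_identical(nrow(res$alerts), 0L)
})

test_that("threshold and rise alerts match a per-minute brute-force oracle", {
  set.seed(11)
  rs <- list(rule("temp_low", "threshold_low", "temperature", threshold = 15),
             rule("temp_high", "threshold_high", "temperature", threshold = 38),
             rule("temp_rise", "delta_rise", "temperature", delta = 2))
  for (i in 1:4) {
    v <- 26 + cumsum(stats::rnorm(1440, 0, 1))
    v <- pmin(pmax(v, -15), 55)
    tr <- temp_day(as.Date("2021-03-16"), v)
    st <- new_engine_state(ruleset = rs, config = engine_config(cooldown_min = 0))
    al <- run_day(st, tr)$alerts
    expect_identical(sort(al$minute[al$rule_id == "temp_low"]), which(v < 15) - 1L)
    expect_identical(sort(al$minute[al$rule_id == "temp_high"]), which(v > 38) - 1L)
    expect_identical(sort(al$minute[al$rule_id == "temp_rise"]),
                     which(diff(v) >= 2))   # oracle: rise completes at minute i
  }
})

test_that("component suppression never increases the total alert count", {
  set.seed(23)
  mk_ruleset <- function(suppress) {
    rs <- default_ruleset()
    lapply(rs, function(x) {
      if (inherits(x, "hs_meta_rule")) x$suppress_components <- suppress
      x
    })
  }
  for (i in 1:5) {
    ev <- dplyr::bind_rows(
      motion_events(sort(sample(0:1439, 30))),
      tibble::tibble(minute = sort(sample(0:1439, 20L)), sensor = "tv_remote"))
    tr <- quiet_day(as.Date("2021-03-16"), events = ev)
    n_sup <- nrow(run_day(new_engine_state(ruleset = mk_ruleset(TRUE)), tr)$alerts)
    n_raw <- nrow(run_day(new_engine_state(ruleset = mk_ruleset(FALSE)), tr)$alerts)
    expect_lte(n_sup, n_raw)
  }
})

test_that("the alteration-day ledger matches the printed half-hour accounting", {
  tr <- fixture_fire_day()
  res <- run_day(new_engine_state(), tr)
  rep <- alert_report(tr, res$alerts)
  expect_identical(rep$range[rep$fire_alerts > 0], "21:30-22:00")
  gas_tbl <- rep[rep$gas_presence_events > 0, ]
  expect_identical(gas_tbl$gas_presence_events,
                   c(3L, 4L, 4L, 2L, 2L, 2L, 3L, 2L, 2L, 2L, 2L))
  expect_identical(gas_tbl$gas_presence_alerts,
                   c(1L, 1L, 1L, 0L, 1L, 1L, 1L, 1L, 1L, 0L, 1L))
  fire_tbl <- rep[rep$fire_events > 0, ]
  expect_identical(fire_tbl$fire_events, c(1L, 9L, 6L, 2L, 1L, 1L, 3L))
})
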