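d0 <- as.Date("2021-03-01")   # a Monday

test_that("binarize_day respects bin edges", {
  tr <- daily_trace(d0, events = motion_events(c(605, 620)))  # 10:05, 10:20
  act <- binarize_day(tr, "motion")
  expect_identical(which(act) - 1L, 10L)
  expect_false(any(binarize_day(daily_trace(d0), "motion")))
  tr2 <- daily_trace(d0, events = motion_events(c(599, 600)))  # 09:59 and 10:00
  expect_identical(which(binarize_day(tr2, "motion")) - 1L, c(9L, 10L))
  expect_error(binarize_day(tr, "temperature"), "threshold")
})

test_that("profiles accumulate day counts and reject duplicate dates", {
  p <- new_profile("motion")
  tr <- daily_trace(d0, events = motion_events(c(500, 510, 1000)))
  p <- accumulate_profile(p, tr)
  expect_identical(p$days_observed, 1L)
  expect_identical(which(p$counts > 0L) - 1L, c(8L, 16L))
  expect_error(accumulate_profile(p, tr), "already accumulated")
  for (i in 1:13) {
    p <- accumulate_profile(p, daily_trace(d0 + i, events = motion_events(c(500, 1000))))
  }
  expect_identical(p$days_observed, 14L)
  expect_identical(max(p$counts), 14L)
  # weekday strata sum to the overall counts
  expect_identical(colSums(p$per_weekday_counts), as.double(p$counts))
})

test_that("range derivation matches an exhaustive per-bin oracle", {
  set.seed(31)
  cfg <- learning_config()
  for (i in 1:25) {
    p <- new_profile("motion")
    p$days_observed <- sample(1:14, 1)
    p$counts <- as.integer(sample(0:p$days_observed, 24L, replace = TRUE))
    rules <- derive_range_rules(p, cfg)
    usual <- p$counts / p$days_observed >= cfg$usual_fraction  # the oracle
    derived_absence <- range_minutes(unlist(lapply(
      Filter(function(r) r$kind == "absence_in_range", rules), `[[`, "ranges"),
      recursive = FALSE))
    derived_presence <- range_minutes(unlist(lapply(
      Filter(function(r) r$kind == "presence_in_range", rules), `[[`, "ranges"),
      recursive = FALSE))
    expect_identical(derived_absence, which(rep(usual, each = 60L)) - 1L)
    expect_identical(derived_presence, which(rep(!usual, each = 60L)) - 1L)
  }
})

test_that("degenerate and TV profiles derive the right rule shapes", {
  p <- new_profile("motion")
  p$days_observed <- 10L
  p$counts <- rep(10L, 24L)                 # always active
  rules <- derive_range_rules(p)
  expect_length(rules, 1L)
  expect_identical(rules[[1]]$kind, "absence_in_range")
  expect_identical(rules[[1]]$ranges, list(make_time_range(0, 1440)))
  # TV: only presence rules (not watching TV is unremarkable)
  ptv <- new_profile("tv_remote")
  ptv$days_observed <- 10L
  ptv$counts <- as.integer(c(rep(0, 20), rep(10, 3), 0))   # TV 20:00-23:00
  tv_rules <- derive_range_rules(ptv)
  expect_true(all(vapply(tv_rules, `[[`, character(1), "kind") == "presence_in_range"))
  expect_identical(range_minutes(unlist(lapply(tv_rules, `[[`, "ranges"),
                                        recursive = FALSE)),
                   range_minutes(list(make_time_range(0, 1200),
                                      make_time_range(1380, 1440))))
})

test_that("reconciliation replaces modifiable ranges and protects permanent rules", {
  old <- list(rule("motion_presence_00h", "presence_in_range", "motion",
                   ranges = list(make_time_range(0, 480))),
              rule("motion_presence_23h", "presence_in_range", "motion",
                   ranges = list(make_time_range(1380, 1440))),
              rule("gas", "event_presence", "gas_presence", mutability = "permanent"))
  derived <- list(rule("motion_presence_00h", "presence_in_range", "motion",
                       ranges = list(make_time_range(0, 540))))
  out <- reconcile_rules(old, derived)
  pres <- Filter(function(r) r$kind == "presence_in_range", out)
  expect_length(pres, 1L)                                   # 23h rule dropped
  expect_identical(pres[[1]]$ranges, list(make_time_range(0, 540)))  # expanded
  gas <- Filter(function(r) r$rule_id == "gas", out)
  expect_length(gas, 1L)
  expect_identical(gas[[1]]$mutability, "permanent")
  bad <- list(rule("gas2", "presence_in_range", "gas_presence",
                   ranges = list(make_time_range(0, 60))))
  bad[[1]]$rule_id <- "gas"
  expect_error(reconcile_rules(old, bad), "permanent")
})

test_that("the life-cycle is silent for 14 days, then alerts and stays stationary", {
  mk_day <- function(date) {
    quiet_day(date, events = motion_events(seq(485, 1375, by = 10)))
  }
  state <- new_engine_state(phase = "calibration")
  profiles <- NULL
  cfg <- learning_config()
  for (i in 0:13) {
    res <- advance_day(state, profiles, mk_day(d0 + i), cfg)
    state <- res$state; profiles <- res$profiles
    expect_identical(nrow(res$alerts), 0L)
  }
  ranges_day14 <- lapply(Filter(function(r) r$sensor == "motion",
                                ruleset_rules(state$ruleset)), `[[`, "ranges")
  # day 15 carries unusual-hour motion: alerting is now live
  tr <- quiet_day(d0 + 14, events = motion_events(c(130, seq(485, 1375, by = 10))))
  res <- advance_day(state, profiles, tr, cfg)
  state <- res$state; profiles <- res$profiles
  # night motion in a dark room: reported either by the presence rule or by
  # the motion + low-light combined notification, which has priority
  expect_gte(count_rule(res$alerts, c("motion_presence_00h", "meta_motion_lowlight")), 1L)
  # identical daily input keeps the ruleset at its fixed point
  for (i in 15:29) {
    res <- advance_day(state, profiles, mk_day(d0 + i), cfg)
    state <- res$state; profiles <- res$profiles
  }
  ranges_day30 <- lapply(Filter(function(r) r$sensor == "motion",
                                ruleset_rules(state$ruleset)), `[[`, "ranges")
  expect_identical(ranges_day30, ranges_day14)
  expect_identical(lifecycle_phase(30L, cfg), "stable")
})

test_that("a pattern confined to Sundays yields a Sunday-specific rule change", {
  rs <- default_ruleset()
  sundays <- d0 + c(6, 13, 20, 27)
  expect_identical(unique(format(sundays, "%u")), "7")
  log <- tibble::tibble(
    timestamp = as.POSIXct(paste(sundays, "18:00"), tz = "UTC"),
    date = sundays, minute = 1080L, rule_id = "motion_absence_16h",
    severity = "alert", message = "")
  rv <- stable_review(log, rs, learning_config())
  expect_identical(rv$report$scope, "weekday")
  expect_identical(rv$report$weekday, 7L)
  ids <- vapply(ruleset_rules(rv$ruleset), `[[`, character(1), "rule_id")
  base <- ruleset_rules(rv$ruleset)[[match("motion_absence_16h", ids)]]
  expect_identical(base$weekdays, 1:6)      # unchanged on other days
  expect_false(any(grepl("motion_absence_16h_wd7", ids)))  # range gone on Sundays
})

test_that("a pattern spread across days shrinks the range for every day", {
  rs <- default_ruleset()
  days <- d0 + c(1, 3, 5, 8, 10, 12, 13)    # 7 alerts over two weeks
  log <- tibble::tibble(
    timestamp = as.POSIXct(paste(days, "23:30"), tz = "UTC"),
    date = days, minute = parse_hm("23:30"), rule_id = "motion_presence_23h",
    severity = "alert", message = "")
  rv <- stable_review(log, rs, learning_config())
  expect_identical(rv$report$scope, "all_days")
  ids <- vapply(ruleset_rules(rv$ruleset), `[[`, character(1), "rule_id")
  # the 23:00-24:00 presence range is dropped: night motion now starts at 00:00
  expect_false("motion_presence_23h" %in% ids)
  expect_true("motion_presence_00h" %in% ids)
})

test_that("review never modifies permanent rules and no-ops without repeats", {
  rs <- default_ruleset()
  days <- d0 + 0:5
  log <- tibble::tibble(
    timestamp = as.POSIXct(paste(days, "10:00"), tz = "UTC"),
    date = days, minute = 600L, rule_id = "gas", severity = "alert", message = "")
  rv <- stable_review(log, rs, learning_config())
  expect_identical(nrow(rv$report), 0L)
  expect_identical(rv$ruleset, rs)
  # two scattered alerts: below the repeat threshold
  log2 <- tibble::tibble(
    timestamp = as.POSIXct(paste(d0 + 0:1, "02:00"), tz = "UTC"),
    date = d0 + 0:1, minute = 120L, rule_id = "motion_presence_00h",
    severity = "alert", message = "")
  rv2 <- stable_review(log2, rs, learning_config())
  expect_identical(rv2$ruleset, rs)
  # random logs over random rules: permanent entries always survive intact
  set.seed(91)
  for (i in 1:10) {
    n <- 30L
    days <- d0 + sample(0:27, n, replace = TRUE)
    log3 <- tibble::tibble(
      timestamp = as.POSIXct(paste(days, "12:00"), tz = "UTC"),
      date = days,
      minute = sample(0:1439, n, replace = TRUE),
      rule_id = sample(c("gas", "motion_presence_00h", "motion_absence_09h"),
                       n, replace = TRUE),
      severity = "alert", message = "")
    rv3 <- stable_review(log3, rs, learning_config())
    ids <- vapply(ruleset_rules(rv3$ruleset), `[[`, character(1), "rule_id")
    expect_true("gas" %in% ids)
    gas_rule <- ruleset_rules(rv3$ruleset)[[match("gas", ids)]]
    expect_identical(gas_rule, rs[[match("gas", vapply(ruleset_rules(rs), `[[`,
                                                       character(1), "rule_id"))]])
  }
})
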