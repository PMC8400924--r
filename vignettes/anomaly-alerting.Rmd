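---
title: "How homesentry decides to alert: rules, cooldown, and learned time ranges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How homesentry decides to alert}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homesentry)
```

`homesentry` is an expert system for ambient-assisted living: it watches
per-minute sensor streams from a single-occupant home and sends alert
messages when the day departs from the resident's own routine. This
vignette explains the model the engine implements, the parameters that
matter, the choices made where the design was genuinely open, and what the
synthetic simulator does and does not emulate.

## The clock and the data model

Everything runs on a minute-resolution clock. A time of day is an integer
in `[0, 1440)`; a time range is half-open, `[start, end)`, and never wraps
midnight — an overnight schedule is expressed as two ranges (23:00–24:00
plus 00:00–07:00). This removes every ambiguity about boundaries: 08:00 is
*not* inside 00:00–08:00, and a range's end minute is exactly when an
absence rule becomes decidable. Event timestamps are truncated to the
minute; sub-minute ordering within a minute is not represented.

A day of data is a `daily_trace`: one reading per periodic channel per
minute (temperature °C, humidity %, pressure hPa, light %, gas level), plus
triggered events (motion, fire, gas presence, TV remote, shock).
`validate_trace()` reports cadence gaps, duplicates, and implausible values
(temperature outside −20…60 °C, percentages outside 0–100) but repairs
nothing: what to do about a broken sensor is a policy question for the
caller, not the validator. Minutes missing from a trace are skipped by the
engine, and consecutive-minute rise rules are inert across such gaps — a
gap is evidence about the device, not about the resident.

## Single rules

The factory catalogue (`default_ruleset()`) covers temperature,
gas/fire, movement, TV use and light; the README tabulates the defaults.
Three semantics deserve precision:

* **Thresholds are strict.** A reading exactly at 15 °C or 38 °C does not
  fire; the catalogue speaks of *exceeding* a limit.
* **Bedtime-vs-daytime temperature uses ≥.** The engine stores the highest
  temperature seen inside the daytime window (09:00–16:00 by default) and,
  at bedtime, alerts when the current temperature is greater than *or equal
  to* that maximum. Equality must fire: a radiator left on typically holds
  the room at the afternoon's plateau rather than above it. The stored
  maximum persists after the window closes — through the evening, past
  midnight, into the early morning — until the *next* day's window opens,
  so a 02:01 check compares against the previous afternoon. With no stored
  maximum yet (fresh deployment, first night) the rule is inert rather than
  comparing against an arbitrary default.
* **Absence is decided when the range closes.** "No movement during usual
  hours" is undecidable mid-range; the engine evaluates it exactly once, at
  the range's end minute (23:59 for ranges closing at midnight), using
  activity flags that reset each midnight. This also makes the alert count
  per range at most one per day, which is how such alerts are audited.

## Meta-rules and priority

A meta-rule couples two component conditions inside a trailing coincidence
window (default 10 minutes) and fires exactly once per coincidence — at the
minute the *later* component occurs. Three are installed by default:
movement + TV use at unusual hours, movement in a dark room (light ≤ 1 %)
at unusual hours, and fire presence + a ≥ 1 °C consecutive-minute
temperature rise, the only rule with `emergency` severity.

Meta-rules have priority: when one covers its components, the component
rules' own alerts for that window are withheld and a single combined
notification goes out (the component cooldown keys are stamped alongside
the meta-rule's). Withholding is causal — a component alert already emitted
minutes before the coincidence completed is not retracted.

Fire is deliberately routed *only* through the meta-rule: flame sensors
produce false positives (direct sunlight among other causes), so a
detection alone is not actionable, while fire plus a simultaneous
temperature rise is. The literal stand-alone fire rule remains in the
catalogue, disabled, and `engine_config(fire_plain_rule_enabled = TRUE)`
restores it.

The 10-minute window is a design choice with a sharp edge: fire detections
at 13:39/13:40 followed by a temperature rise starting at 13:51 must *not*
coincide, while a 21:56 detection inside a 21:54–21:59 rise must. Any
window in roughly the 3–11 minute band separates these cases; 10 minutes
sits safely inside it and is configurable.

## The cooldown gate

Alert messages of the same type must not repeat until 30 minutes have
elapsed. The gate implements this at the granularity of wall-clock windows
of `cooldown_min` minutes aligned to midnight: an alert for a key is
allowed only when the window containing *now* opened at least
`cooldown_min` minutes after the key's last emission. Two guarantees
follow, and both are what an alert ledger organised in half-hour ranges
displays: at most one alert per key per aligned window, and consecutive
same-key alerts always ≥ 30 minutes apart.

The window-aligned formulation, rather than a bare
`now − last ≥ cooldown`, is load-bearing. Consider gas detections with an
alert sent at 13:56 and the next detection at 14:29: the bare rule would
emit (33 minutes elapsed), but the 14:00–14:30 window opened only 4 minutes
after the alert, so the gate stays closed until 14:30. A sustained
exceedance (say a bedtime temperature holding above the daytime maximum
for 16 consecutive minutes) likewise collapses to a single alert instead
of one per minute. Keys are per rule id, so motion-presence and
TV-presence throttle independently; `cooldown_min = 0` disables throttling
entirely (used when comparing against per-minute oracles).

## The learning life-cycle

Usual/unusual time ranges are learned, not configured. A
`behavior_profile` counts, per hour-of-day bin, on how many observed days
the sensor produced at least one event in that bin (plus a per-weekday
stratification). An hour is **usual** when active on at least
`usual_fraction` (default 0.5) of observed days. Derivation is a
partition: maximal runs of usual hours become absence rules, maximal runs
of unusual hours become presence rules; for the TV remote only presence
rules are built, since not watching TV is unremarkable. Re-deriving from
the cumulative profile *is* the "expanding or decreasing" of ranges: it is
deterministic, order-independent, and reaches a fixed point under
stationary behaviour (asserted in the tests). An incremental
edge-nudging mode was considered and rejected: without a principled update
formula it is order-dependent and drifts.

The life-cycle phases are day-counted: **calibration**
(`calibration_days = 14`) runs the whole engine but suppresses emission —
the state, profiles and rules still update; **readjustment** (another 14
days) alerts while still reconciling daily; **stable** leaves the ruleset
alone except through review. Fourteen days give each weekday only two
observations, which is why calibration learns a single all-days profile;
weekday structure is handled later, by review, where the evidence for it
actually accumulates.

**Stable review** groups the trailing `review_window_days = 28` of alerts
by rule and hour bin. A pattern repeating `repeat_threshold = 3` times
means the "unusual" behaviour is in fact routine and the rule should yield.
Scope is decided by concentration: if one weekday accounts for the repeats
and the remaining alerts alone would not cross the threshold, the rule is
split — unchanged on other weekdays, shrunk (or dropped) on that weekday;
otherwise the range shrinks for every day. A plain threshold comparison on
both groupings cannot express this (a weekday group crossing always drags
the all-days group across too, since its counts are a subset), so
concentration is the operative test: four absence alerts on four
consecutive Sundays produce a Sunday-specific change, while seven
night-motion alerts spread over two weeks remove the 23:00–24:00 presence
range for every day. Permanent rules (gas, fire, the fire meta-rule) are
never modified. Threshold-type rules (15 °C, 38 °C, light levels) are
declared "modifiable" by the catalogue but no adaptation procedure is
defined for them here; they are exposed as configuration instead of
guessing one.

## The simulator

`simulate_day()` generates the statistical structure the engine assumes:
motion as a Poisson process (default 20 events/h) inside the active period
`[wake, sleep)`, zero outside, silenced by weekday-specific away windows;
TV-remote events (30 events/h) inside evening TV windows; temperature as a
sinusoidal diurnal curve (coldest 04:00, warmest 16:00, amplitude 3 °C
around 19 °C) with optional heating episodes that ramp to a setpoint; light
at three levels (day 60 %, evening 40 %, night 0 %); humidity, pressure and
gas level as constants plus noise. Per-channel noise is Gaussian;
the temperature default (SD 0.05 °C) is two orders of magnitude below the
2 °C rise rule, so noise cannot trigger it. Every channel draws from its
own RNG stream derived from `(seed, date, channel)`, so adding a channel or
regenerating a single day never perturbs the others, and identical
`(config, seed)` yield byte-identical traces.

`inject_anomaly()` perturbs one channel in one scope and nothing else:
gas/fire events, night motion, a day-long absence, a temperature spike
whose qualifying ≥ 2 °C pair completes at a chosen minute, or heating held
above the day's maximum through a night range (entered via a ramp that
stays below the rise threshold, so only the intended rule fires).

Two deterministic fixtures encode the worked examples the package's
acceptance checks replay. `fixture_fire_day()` holds fire detections at
13:39, 13:40 and 21:56, gas detections in eleven half-hour windows
including 13:56 and 14:29, and three abrupt temperature rises completing at
14:00, 19:36 and 21:59. Times not individually printed in the source
schedule are fixed deterministically, and the choice is constrained — bin
midpoints do not work. Two placements are forced by the cooldown
arithmetic: the 13:00–13:30 gas alert must fall exactly at 13:00 (any
later and the 13:56 alert could not clear the gate), and all four
13:30–14:00 gas detections must lie at 13:56–13:59 (an earlier one would
have alerted first). Within the 21:54–21:59 rise the per-minute increments
are 0.9, 0.9, 1.0, 0.9, 2.0 °C: the only pair reaching 1 °C before the
final one completes at 21:57, one minute after the 21:56 fire detection,
so the fire meta-rule fires exactly once, at 21:57, while the stand-alone
2 °C rule fires only at 21:59. `fixture_night_temp()` builds two days:
afternoon maximum 21.8 °C, then 21.9 °C touched at exactly 02:01 and 03:33
the following night (two alerts — the exceedances are discrete instants);
afternoon maximum 23.8 °C, then 23.9 °C held 23:17–23:32 (one alert — the
cooldown collapses the sustained exceedance).

What the simulator does *not* emulate: multi-occupant homes and visitors,
physically realistic thermal dynamics (heating is a ramp-and-hold, not a
building model), correlated sensor failures, humidity/pressure/shock
dynamics beyond noise, and seasonal or weekend structure unless configured
through away windows. Passing tests therefore demonstrate that the engine
and learner behave as specified under the assumed structure — Poisson
activity inside crisp hour-aligned schedules — not that real homes are this
clean. In particular, parameter recovery is exact at 60-minute resolution
because the generator's schedules are hour-aligned and its rates make an
active hour essentially certain to register (at 20 events/h the chance an
active hour stays silent is e^−20); ragged real schedules would recover
only to bin resolution.

## Numerical and degenerate-input choices

* Hour bins (`bin_width = 60`) because the rule vocabulary is whole hours;
  any divisor of 1440 works.
* `usual_fraction = 0.5`: an hour is usual when active on at least half of
  observed days — the natural majority rule when no threshold is given.
* A profile in which every hour is usual derives a single all-day absence
  rule and no presence rules (and vice versa).
* Engine time is monotone; feeding a minute at or before the last
  processed one, or a trace whose date does not follow, is a contract
  error, not a silent reorder.
* During calibration the cooldown registry is not stamped (nothing was
  emitted), so the first readjustment-phase alert is not accidentally
  throttled by a silent predecessor.
* Ranges produced by learning and review are normalised (sorted, merged,
  disjoint); review changes that empty a rule's range list remove the rule.
* The problem sizes exercised in the test suite — 14-day calibrations,
  50 random schedules for recovery, 1,000 random streams for the cooldown
  invariant, brute-force oracles over single days — were chosen as the
  smallest sizes at which every phase transition and every throttling edge
  case is actually reached.

## Known limitations

The engine trusts its sensors: a stuck PIR reads as continuous presence
and a dead one as absence, and no cross-sensor plausibility filtering is
attempted beyond ingestion bounds (`validate_trace()` reports, the caller
decides). Overnight schedules are expressible only as range pairs, so a
resident whose *active* period wraps midnight (night-shift patterns) needs
hand-written rules. Alert delivery is a sink abstraction — a log file or
the alert tibble; transport is out of scope. Adaptation of numeric
thresholds (temperature, light) is exposed as configuration, not learned.
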