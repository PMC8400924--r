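Package: homesentry
Title: Rule-Based Anomaly Alerts from Ambient Home Sensor Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An expert-system core for ambient-assisted-living monitoring of a
    single-occupant home. Consumes per-minute ambient sensor readings
    (temperature, humidity, pressure, light, gas level) and event-triggered
    detections (motion, fire, gas presence, TV-remote use, shock), evaluates a
    catalogue of unusual-behaviour rules and coincidence meta-rules over a
    streaming minute clock, and emits cooldown-throttled alert messages.
    Usual/unusual time-range rules are learned from daily activity profiles
    through a calibration/readjustment/stable life-cycle and revised when an
    alert repeats in the same weekly pattern. Includes a synthetic resident
    simulator that generates daily traces with configurable schedules, Poisson
    activity processes and injectable anomalies, plus a command-line interface
    for simulation, calibration, monitoring and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
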