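Package: rtpkit
Title: Game-Based Assessment of Manual Dexterity: Trial Simulation, Logging
    and Performance Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for computer game-based assessment of manual dexterity in
    rehabilitation. Generates standardized cyclic-tracking and motor-skill-game
    assessment trials, records 100 Hz event-synchronized session logs, and
    computes the associated performance measures: total and average residual
    tracking error, half-cycle movement amplitude and its coefficient of
    variation, success rate, movement onset time, movement time and movement
    error. Includes a configurable player simulator for validation and
    parameter-recovery studies, pre/post outcome tables with percent change,
    and test-retest reliability reporting (ICC, SEM, minimal detectable
    change). A command-line interface ties simulation, analysis and reporting
    together with reproducible seeds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
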