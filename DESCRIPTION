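Package: sitpose
Title: Posture Monitoring and Transition Analysis for a Pressure-Sensor Instrumented Chair
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates, calibrates and classifies multi-channel seat and
    backrest pressure-sensor recordings acquired while a seated participant
    performs a scheduled Stroop colour-word task, and analyses how sitting
    postures change as cognitive engagement increases.  The pipeline covers
    the Stroop timeline and its three analysis intervals, a synthetic
    eight-channel voltage-trace generator with per-channel baselines and
    injectable sensor failures, adaptive per-test activation thresholds
    (midpoint of the no-load and fully-loaded baselines), 1 Hz moving-average
    filtering, activation-pattern posture lookup with quality control, and
    paired categorical transition statistics: posture-transition contingency
    tables, continuity-corrected McNemar tests under a discordant-count
    eligibility condition, and Bowker's global test of symmetry.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
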