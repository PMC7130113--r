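Package: tactoj
Title: Tactile Temporal Order Judgment Simulation and Psychometric Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing tactile
    temporal order judgment (TOJ) experiments in unilateral chronic pain
    cohorts. Builds the alternating crossed/uncrossed block schedule,
    simulates cumulative-normal observers with a crossed-hands deficit,
    runs a double random staircase for between-hand intensity matching,
    estimates the point of subjective simultaneity (PSS) and the just
    noticeable difference (JND) by probit regression on response
    proportions, applies the standard exclusion filters, and provides
    group-level tests plus a simulation-based parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
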