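Package: hvemsim
Title: Monte-Carlo Simulation of Home Video-EEG Monitoring Duration in Epilepsy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates annual daily seizure time-courses for pediatric and
    adult epilepsy cohorts (1-30 seizures/month) and estimates how many days
    of continuous home video-EEG monitoring (HVEM) are needed to capture 1, 3,
    or 5 seizures on distinct calendar days. Seizure frequencies are drawn
    from an interval-discretized probability density grid; adult time-courses
    optionally carry multidien seizure cycles (7/15/20/30-day periods) with
    phase-locked allocation of a fraction of seizures to the active
    half-cycle. Includes a deterministic surrogate-grid calibrator matched to
    published monthly summary statistics, cohort-level summary and comparison
    reports, and weekly capture-percentage tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
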