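Package: actipat
Title: Wrist Actigraphy Activity Patterns in Rheumatoid Arthritis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving physical-activity pattern metrics from
    epoch-level wrist-accelerometer data and screening them for group
    differences in matched case-control cohorts, with rheumatoid arthritis
    as the motivating condition. Includes a circadian semi-Markov simulator
    of activity-state sequences and acceleration magnitudes, epoch-level
    preprocessing (ENMO magnitude, non-wear detection, imputation, wear-time
    validity), activity labeling with night-time lying-down consolidation and
    ambulatory bout extraction, sustained-activity bout detection with a
    brute-force reference detector, a 145-metric registry spanning total
    volume, morning, night-time and fragmentation domains, categorical 2:1
    nearest-neighbour matching, log-ratio screening with Welch confidence
    intervals, ANOVA/ANCOVA adjustment, wake-aligned population activity
    profiles, and standardized principal component analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
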