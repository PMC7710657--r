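Package: actirhythm
Title: Circadian Rhythmicity and Sleep Analysis for Insect Activity Monitors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for activity-monitor recordings of insect
    foragers: parsing of DAM-style tab-separated monitor files and a
    canonical long CSV, light-schedule phase mapping (light:dark
    entrainment followed by constant darkness), an autocorrelation-based
    rhythmicity statistic with rhythmic/arrhythmic classification,
    sleep-bout detection from sustained inactivity, day/night activity
    and sleep summaries, actogram matrices, group-level statistics
    (one-way ANOVA with Tukey contrasts, two-sample t tests), and a
    seeded synthetic-cohort generator with known circadian and sleep
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
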