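Package: fabas
Title: Fetal Autonomic Brain Age Scoring from Beat-to-Beat Heart Rate Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Heart rate variability analysis of fetal beat-to-beat (NN) interval
    recordings at millisecond resolution. Provides CTG-compatible short- and
    long-term variability (STV/LTV) with Dawes-Redman normality criteria,
    the five fABAS maturation indices (fluctuation amplitude, skewness of the
    instantaneous heart rate, pNN5, ln VLF/LF band-power ratio, and a
    coarse-grained lag-1 auto mutual information complexity measure),
    rule-based behavioral-state (heart rate pattern) segmentation,
    acceleration/deceleration pattern segmentation within quiet sleep,
    stepwise weighted regression models that estimate gestational age from
    the indices, and per-age normograms. A seeded synthetic-recording
    generator with ground truth supports testing and calibration end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
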