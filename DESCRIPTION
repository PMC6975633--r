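Package: marsbmd
Title: Predicting Astronaut Femoral-Neck Bone Density Loss in Long-Duration Spaceflight
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Fits a fixed-plateau exponential decay model to published
    astronaut femoral-neck bone-mineral-density (BMD) losses by weighted
    nonlinear least squares, derives the loss kinetics (half-life, time
    constant), predicts losses for opposition- and conjunction-class Mars
    mission durations, propagates them to T-scores across sex, ethnicity
    and age reference groups, and classifies fracture risk under WHO and
    NASA criteria.  Includes asymptotic and bootstrap confidence
    intervals, pointwise prediction bands, and a synthetic astronaut
    cohort generator for parameter-recovery and coverage studies.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
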