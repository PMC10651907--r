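Package: activegaze
Title: Active-Vision Scanpath Analysis for a 3D Same-Different Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mobile eye-tracking experiments in which a
    freely moving observer compares two physical block-built (polycube) objects.
    Synchronizes a 120 Hz head-pose stream with a 50 Hz gaze stream, detects
    fixations with a velocity-threshold (I-VT) classifier, assigns fixations to
    objects or environment from world-frame gaze rays, computes per-trial
    behavioral measures (response time, fixation counts and groupings,
    primary/secondary fixation ratio, head-movement extent, accuracy), and runs
    the statistical layer (repeated-measures ANOVA, binomial mixed model for
    accuracy, trial-block learning effects). Includes a synthetic experiment
    generator with full ground truth so every stage is testable without
    recorded human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
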