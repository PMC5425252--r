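Package: metacogsim
Title: Metacognition Analysis and Simulation for Confidence-Rating
    Psychophysics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for visual metacognition experiments in
    which perceptual accuracy is held near 71 percent by adaptive
    staircases and subjects rate decision confidence on a continuous
    scale. Computes type-II metacognitive sensitivity (AUROC2) and type-I
    signal-detection metrics (d-prime, criterion), applies standard trial-
    and subject-level exclusion rules with equal-count confidence binning,
    and runs group-level inference including ANOVA, ANCOVA, mixed ANOVA,
    pooled t-tests with Cohen's d, and a JZS/unit-information Bayes-factor
    t-test. Includes a generative two-stage signal-detection observer with
    an explicit metacognitive-noise parameter and a dual adaptive
    staircase, for simulating full cohorts and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
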