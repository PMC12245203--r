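Package: muscleclock
Title: Muscle Age Acceleration Clock from EWGSOP2 Motor-Functional Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a sex-specific biological age clock ("Muscle Age") from the
    EWGSOP2 sarcopenia test battery (handgrip strength, five-times sit-to-stand,
    skeletal and appendicular muscle mass, gait speed, SPPB, timed up-and-go,
    six-minute walk, calf circumference) using permutation-averaged elastic-net
    regression with cross-validated hyperparameter selection, derives Muscle Age
    Acceleration (MAA) as the residual of predicted on chronological age, and
    trichotomizes participants into decelerated, normal and accelerated agers by
    a percentile rank rule. Also provides the Ishii sarcopenia screening score
    and probability, the Levine phenotypic age (PhenoAge) calculator with its
    age-acceleration residual (PhenoAA), a two-way ANOVA group-comparison layer
    with Bonferroni-adjusted pairwise contrasts, and a seeded synthetic-cohort
    generator with generative ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    car,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
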