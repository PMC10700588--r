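Package: affectmap
Title: Scoring and Structural Modelling of Emotion Experience, Representation
    and Recognition Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing a battery of behavioural tasks probing how
    emotions are experienced, visually represented, and recognised. Enumerates
    the task designs (pairwise affect-similarity ratings, forced-choice
    intensity triplets with attention traps, speed-dial attribution to
    point-light facial expressions, visual speed matching, and point-light
    emotion recognition), scores them (SMACOF multidimensional-scaling
    landscapes with within/between-cluster distances, transitivity-based
    choice consistency, representational consistency and differentiation,
    matching difficulty, recognition accuracy), and searches for a structural
    model of emotion recognition via shadow-feature random-forest screening,
    sequential maximum-likelihood structural-equation building, and systematic
    path-reversal comparison under a BIC evidence rule. A seeded synthetic
    cohort generator with the generative structure the analysis assumes makes
    every stage testable end to end, with parameter recovery as the
    acceptance surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
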