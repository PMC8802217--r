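Package: burstloco
Title: Burst Locomotor Performance, Muscle Power Capacity, and Ontogenetic
    Scaling from Force-Plate Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for burst (accelerative) locomotion measured on
    force plates with synchronized marker tracking, motivated by ontogenetic
    studies of escape performance in small mammals. Computes per-trial
    center-of-mass acceleration, escape speed and mechanical power from
    ground-reaction-force impulse integration with kinematically seeded and
    kinetically optimized initial velocity; estimates hindlimb extensor power
    capacity from muscle architecture (PCSA, maximum isometric stress, fascicle
    shortening velocity); fits ontogenetic quadratic performance-mass models
    with heteroscedastic errors, peak (vertex) estimation with bootstrap
    confidence intervals, log-log allometry, repeatability (ICC), effect sizes,
    Box-Cox standardization, one-tailed correlation and Fisher-z power
    analysis; fits recursive standardized path models by maximum likelihood
    with chi-square, RMSEA and CFI fit indices and stepwise pruning; and
    projects constant-acceleration escape scenarios. Includes a synthetic
    trial/cohort generator with known ground truth for parameter-recovery
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    lme4,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
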