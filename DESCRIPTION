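Package: hctraj
Title: Latent-Class Trajectory Modelling of Fetal Cranial Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies latent classes of fetal head-circumference growth from
    longitudinal ultrasound-derived z-scores using a finite mixture of linear
    mixed models with quadratic B-spline mean trajectories and a shared random
    intercept, fitted by an EM algorithm on the structured compound-symmetry
    likelihood. Provides BIC-based model selection with a smallest-class rule,
    posterior-probability diagnostics (average posterior probability and odds of
    correct classification), and class-specific association models for 2-year
    growth, neurodevelopmental, behavioural, vision and motor-milestone outcomes
    (linear, overdispersion-corrected modified Poisson, and Cox proportional
    hazards regression) with Benjamini-Hochberg false-discovery-rate control.
    A seeded synthetic-cohort generator reproduces the longitudinal design of a
    multi-site fetal growth study so that every stage can be exercised and
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    splines,
    graphics,
    stats,
    survival,
    sandwich,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme
Config/testthat/edition: 3
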