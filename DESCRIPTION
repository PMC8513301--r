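Package: smidisparity
Title: Disparities in Police Use of Force for Persons with Serious Mental Illness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for measuring disparities in police use of
    force and suspect injury experienced by persons with serious mental
    illness (SMI). Provides a rule-based SMI case definition from structured
    survey items (CIDI diagnosis, functional impairment, duration), synthetic
    small-area estimation of SMI prevalence by projecting a national-survey
    logistic regression onto area-level covariate profiles, and Bayesian
    hierarchical negative-binomial regression with exposure offsets yielding
    relative risks with credible intervals for SMI status and for race.
    Includes a full synthetic-data generator with known ground truth so the
    pipeline can be exercised and validated end to end without restricted
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
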