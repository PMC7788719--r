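Package: ordprof
Title: Ordinal Outcome Analysis for Hospital Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework quantifying the efficiency gain of analysing
    hospital outcome differences on a full ordinal scale with proportional-odds
    regression instead of dichotomized endpoints with binary logistic
    regression. Provides synthetic traumatic-brain-injury (Glasgow Outcome
    Scale) and stroke (modified Rankin Scale) cohort generators, injection of
    per-hospital center effects on the cumulative-logit scale, fixed-effect
    center-effect estimation with confidence-interval based outlier detection,
    Monte-Carlo power and type-I-error experiments, and translation of
    detection-rate curves into equal-power sample-size reductions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    nnet,
    yaml,
    jsonlite,
    parallel
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
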