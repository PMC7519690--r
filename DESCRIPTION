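Package: bbci
Title: Biometric Body Condition Indices and Their Physiological Correlates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes eight biometric body condition indices for wild
    carnivores (ratio indices, allometric-regression residual indices and
    the scaled mass index), standardizes indices and blood physiology
    parameters to species-specific percentiles via maximum
    goodness-of-fit distribution fitting and beta-PERT reference-range
    fusion, and relates condition to hematology and serum biochemistry
    with a logit-scale Bayesian hierarchical model carrying an
    inter-species random intercept. Includes a synthetic multi-species
    data generator with known ground truth so the whole pipeline can be
    exercised and calibrated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    fitdistrplus,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rjags,
    coda,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
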