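Package: dyadstress
Title: Dyadic State-Space Modelling of Subjective Stress and Hair Cortisol
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multimethod stress assessment studies in couples:
    scoring of weekly hassle, perceived stress and chronic stress
    questionnaires sampled at mixed frequencies by two informants,
    McDonald's omega reliability, meta-analytically pooled retest
    correlations, a Bayesian dyadic state-space (dynamic factor) model of
    latent subjective stress fitted by Gibbs sampling, and a lag-scan
    regression validating hair cortisol concentration as a retrospective
    stress marker. Includes a synthetic-data generator that reproduces the
    full study design so every stage can be exercised with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    rjags,
    coda,
    metafor,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
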