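Package: fvtqtl
Title: Function-Valued Trait Growth Curves, QTL Mapping, and
    Genotype-to-Phenotype Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits hierarchical Bayesian logistic growth curves to
    longitudinal leaf measurements on a thermal-time (degree-day) axis and
    analyzes the fitted curve parameters (growth rate, final size, growth
    duration, inflection timing) as function-valued traits in a
    recombinant inbred line population.  Provides shrinkage (BLUP)
    genotype means and random-effect likelihood-ratio tests, Haley-Knott
    interval mapping with permutation thresholds and iterative multi-QTL
    search, QTL-by-environment Type III F tests, prediction of whole
    growth curves for held-out genotypes from additive QTL effects scored
    against Bayesian credible envelopes, a synthetic-data generator with
    known truth for every stage, and utilities for reflectance spectra
    (binning, red:far-red ratio, configurable band-math indices).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils
Suggests:
    car,
    deSolve,
    jsonlite,
    lmerTest,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
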