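Package: sustainr
Title: Subtype and Stage Inference for Regional Brain Atrophy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Data-driven subtyping and staging of neurodegenerative atrophy
    from regional brain volumes. Implements covariate-adjusted w-scoring
    against a control cohort, a threshold-event (z-score) subtype-and-stage
    progression model fitted by expectation-maximization with greedy sequence
    optimisation, Markov chain Monte Carlo uncertainty estimation,
    cross-validated selection of the number of subtypes, probabilistic
    per-visit subtype and stage assignment, Hellinger-distance similarity
    between positional-variance distributions with randomized reference
    values, longitudinal stability summaries, and a synthetic cohort
    generator for end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
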