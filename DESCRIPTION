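Package: plaidclass
Title: Model-Based Classification of Component and Pattern Responses to
    Plaid Stimuli
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies single-neuron responses to drifting grating and
    plaid stimuli as component- or pattern-selective. Implements a
    Bayesian model-comparison framework operating on single-trial
    responses (two-sample Kolmogorov-Smirnov acceptance tests with
    Holm-Bonferroni correction, Monte-Carlo kernel-density likelihoods,
    deciban model ranking), the classical partial-correlation
    classifier, modulation and selectivity indices, peak-response
    extraction from calcium dF/F traces, a pairwise response-similarity
    bootstrap ("number of rules" analysis) with a two-dimensional
    two-sample Kolmogorov-Smirnov test, and a seeded synthetic-data
    generator with ground-truth response classes for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
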