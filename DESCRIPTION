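Package: neglectr
Title: Active-Inference Simulation of Visual Neglect in the Saccadic
    Cancellation Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates the saccadic cancellation task used at the bedside to
    assess hemispatial neglect, using a discrete-state active-inference
    (Markov decision process) agent that selects saccades by minimising
    expected free energy. Provides a flat 64-location generative model and a
    multiscale (quadrant / subquadrant / cell) variant, Dirichlet likelihood
    learning as a synaptic working memory for cancelled targets, three
    in-silico lesions (likelihood-count inflation, policy-prior bias, and
    proprioceptive-preference bias) that reproduce neglect-like rightward
    search, and a Bayesian model-comparison pipeline that decodes the lesion
    from simulated scanpaths via per-saccade log evidence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
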