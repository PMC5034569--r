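Package: coagstate
Title: Latent Disease-State Modelling of Trauma-Induced Coagulopathy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies latent disease states from sparse longitudinal blood
    coagulation panels (clotting factors II, V, VII, VIII, IX, X, antithrombin
    III, protein C, PT and PTT) using a Gaussian-emission hidden Markov model
    fitted by an EM algorithm that integrates over missing-at-random
    measurement components via conditional Gaussian moments. Provides cohort
    preprocessing on a 24-hour grid, BIC selection of the number of states over
    multi-restart fits, Viterbi trajectory decoding, state occupancy and
    outcome-attribution summaries, a transition-graph stage partition, and a
    calibrated synthetic-cohort generator for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
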