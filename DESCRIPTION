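Package: rlwmpheno
Title: Neurocomputational Phenotyping with the RL-WM Model and Model-Based EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for neurocomputational phenotyping of instrumental learning:
    a reinforcement-learning plus working-memory (RL-WM) mixture model of
    trial-by-trial choice in blocked associative-learning tasks, constrained
    multi-start maximum-likelihood fitting with an integer working-memory
    capacity grid, trialwise model-based EEG analysis (mass-univariate robust
    regression over channels and timepoints with cluster-based sign-flip
    permutation correction and trialwise neural-marker extraction), a
    synthetic-cohort generator producing behavior and multichannel epochs with
    planted group structure, and downstream mixed-effects group analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    lme4,
    jsonlite,
    rhdf5
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
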