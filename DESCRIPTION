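Package: reachstates
Title: Hidden Markov Neural-State Segmentation and Decoding for Delayed
    Reaching Spike Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying discrete neural states in population
    spiking activity recorded during an instructed-delay reaching task and
    for decoding task phase and reach target from short fragments of
    activity.  Implements constrained (feedforward/Bakis) hidden Markov
    models over single-symbol spike emission sequences, including
    Baum-Welch and supervised parameter estimation, a consistency analysis
    for selecting the number of states, and a boosted 28-state decoder
    that merges target-specific models.  Support Vector Machine and LSTM
    baselines, a task-structured Poisson spike-train simulator, and an
    evaluation battery (accuracy against shuffle chance, confusion and
    error-pattern analysis, Davies-Bouldin clustering indices,
    neuron-dropping and spike-shuffling robustness curves) round out the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
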