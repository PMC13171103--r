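Package: setshift
Title: Simulation and Population Decoding of Prefrontal Calcium Activity During Attentional Set-Shifting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyze medial prefrontal cortex (mPFC)
    population calcium activity recorded during attentional set-shifting.
    Provides a synthetic session generator with planted single-neuron tuning
    (choice, trial history, switch state) and group-level effects; per-neuron
    z-scoring, event-aligned binning and calcium-transient metrics; ROC/AUC
    tuning classification with a label-permutation null and chi-squared group
    comparisons; bootstrap PCA state-trajectory geometry (Euclidean distance
    and per-component similarity between early rule-learning and late
    rule-following states); a two-state diagonal-Gaussian hidden Markov model
    decoder (K-means initialization, Baum-Welch, Viterbi) under a
    neuron-subsampling and trial-balancing bootstrap; and an L2-penalized
    logistic decoder of trial outcomes from leading principal components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
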