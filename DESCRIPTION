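Package: gcnppi
Title: Protein-Protein Interaction Prediction from Sequence and Network
    Position
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-protein interactions by combining a
    fixed-length one-hot encoding of each protein's amino-acid sequence
    with a position embedding obtained from a one-layer graph
    convolutional network over the training interaction graph. Protein
    pairs are scored by a twin-branch fully-connected network with a
    joint softmax head, trained end-to-end by stochastic gradient
    descent. Includes leakage-safe stratified k-fold cross-validation,
    precision/recall/accuracy and precision-recall-curve (auPR)
    evaluation, ablation modes that disable either input channel, and a
    synthetic-data generator that plants interaction signal jointly in
    sequence motifs and graph topology.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
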