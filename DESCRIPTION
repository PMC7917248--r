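Package: tripletDTA
Title: Three-Tunnel Deep Neural Network for Drug-Target Binding Affinity
    and Drug Repositioning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts drug-target binding affinity (pKd) with a three-tunnel
    deep neural network: a multilayer-perceptron encoder over 1024-bit
    extended-connectivity fingerprints of drug molecules, a one-dimensional
    convolutional encoder over one-hot encoded protein sequences, and a
    protein-anchored triplet loss over positive and negative drug samples.
    Includes readers and writers for the four-file extended-dataset layout
    (drug SMILES table, protein FASTA, dense Kd matrix, negative-sample
    SMILES matrix), negative-sample matrix construction, concordance-index
    and mean-squared-error evaluation, a virtual-screening ranking pipeline
    with molecular-weight and exclusion-list filters, and a synthetic-data
    generator with planted bilinear structure so the full pipeline runs
    without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
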