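Package: rnaligand
Title: Dual-View Cross-Attention Networks for RNA-Small Molecule Binding
    Affinity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts RNA-small molecule binding affinity (pKd) with a
    fine-grained, dual-view neural architecture: nucleotide-level RNA
    encoders (graph attention over secondary-structure contact maps and a
    multiscale 1D convolutional sequence encoder) and atom-level molecule
    encoders (graph convolution over the chemical graph and a Transformer
    over atomic SMILES tokens), fused by a cross-attention Transformer
    with segment embeddings. Ships the full evaluation harness (stratified
    and blind cross-validation splits, leakage filtering for independent
    tests, regression and classification metrics), attention-based
    interpretability rankings, and a seeded synthetic-data generator so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ChemmineR,
    dplyr,
    ggplot2,
    jsonlite,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
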