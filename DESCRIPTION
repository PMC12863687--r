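Package: momlm
Title: Multi-Omic Masked Language Models for Protein-Nucleic Acid Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale framework for jointly modeling protein and nucleic
    acid sequences with a single non-causal transformer encoder trained by
    masked language modeling. Provides modality-disjoint byte-pair and
    single-character tokenizers with exact span bookkeeping, a rotary-position
    encoder with maximal-update-parameterization (muP) initialization and
    learning-rate scaling, fine-tuning heads for binding free-energy (dG)
    regression, per-residue protein-nucleotide contact tagging, sequence
    classification and pairwise contact maps, exact residue-token label
    transforms for subword tokenizations, homology-aware cross-validation
    splitting with BLOSUM62 alignment scores, position-frequency-matrix
    consensus extraction and mutation scanning, and two interpretability
    probes: a contrastive low-rank modality-invariance probe and a frozen
    attention-map convolutional contact probe. A seeded synthetic-data module
    generates gene-protein pairs, binding datasets with a known recoverable
    energy model, and toy contact structures so every component is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
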