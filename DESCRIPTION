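Package: raackit
Title: Reduced Amino Acid Alphabet Sequence Classification Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sequence-based binary protein classification built on reduced
    amino acid alphabets. Protein sequences are rewritten over a reduced
    alphabet (an ordered partition of the 20 standard residues into k
    groups), encoded as overlapping N-peptide composition vectors
    (N = 1, 2, 3), ranked by one-way ANOVA F-score, pruned by incremental
    feature selection, and classified with an RBF-kernel support vector
    machine trained by an in-package SMO solver. Ships the 18-scheme
    information-maximization reduction family (sizes 2-19), a stratified
    cross-validation engine with Sn/Sp/Acc/ROC/AUC reporting, a full
    scan-select-train-evaluate pipeline with a command line interface, and
    a synthetic FASTA generator that plants class-conditional compositional
    bias in reduced space for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
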