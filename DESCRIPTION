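Package: tlmhc
Title: Transfer Learning for Peptide-MHC Stability and Immunogenicity
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for class-I peptide-MHC prediction by transfer learning.
    Pretrains a two-head multilayer-perceptron predictor (binding-affinity
    regression plus eluted-ligand classification) on binding-style data with
    proteome-derived decoys, then fine-tunes it to peptide-MHC kinetic
    stability and peptide immunogenicity. Includes dataset curation
    (decoy generation, strong-binder filtering, random-negative
    augmentation, per-allele label balancing, stratified nested
    cross-validation), evaluation protocols (merged-fold Pearson and
    Kendall tau-b, AUROC/AUPRC, Top-N counts, Kolmogorov-Smirnov
    distribution comparison, threshold-mean curves), score-derived
    sequence-motif extraction, and a synthetic multi-task data generator
    for end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
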