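Package: xshadow
Title: Probabilistic Integration of Somatic Mutations and Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayes modelling of whether somatic mutations impact
    gene expression in cis (on the mutated gene itself) or in trans (on the
    genes connected to it in a weighted influence graph).  Expression of each
    gene across a tumour cohort is described by a three-component Student's-t
    mixture (down-regulated / neutral / up-regulated); exact posterior
    probabilities that a gene's mutations dysregulate expression (P(D)), that
    an individual mutation does so in an individual patient (P(F)), and that
    a connected gene is dysregulated (P(G)) are computed by sum-product
    belief propagation on the tree-structured model, with parameters learned
    by expectation-maximisation.  Companion procedures cover expressed-gene
    filtering, Gaussian-process compensation of copy-number cis effects,
    influence-graph conditioning, mixture-of-binomial annotation of tumour
    suppressor and oncogene mutation patterns, a generative simulator with
    AUROC benchmarking and permutation null analysis, and post hoc patient
    stratification (Hartigan's dip test), cross-tumour recurrence tests and
    hypermutator flagging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mclust,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
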