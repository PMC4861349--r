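Package: conformerQA
Title: Conformational-Diversity-Aware Assessment of Protein Structure Models
Version: 0.1.0
Authors@R: person("SBG", "Maintainers", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools to evaluate populations of computational protein models
    (decoys) against the native conformational ensemble of their target
    rather than a single reference structure. Given two experimentally
    determined conformers of a target and a set of decoys, the package
    computes optimal rigid-body superpositions and three standard
    structural-similarity measures (Calpha-RMSD, GDT_TS, TM-score), ranks
    decoys against both conformers, quantifies ranking divergence with
    Spearman's rank correlation, selects and cross-compares best decoys,
    and classifies whether the decoy population resolves distinct members
    of the native ensemble. A synthetic-data module generates hinge-motion
    conformer pairs and noisy decoy clouds with ground-truth labels so the
    whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
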