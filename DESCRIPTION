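Package: eqtloverlap
Title: Overlap of QTL and eQTL via Local Genomic Breeding Values
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying the overlap between
    quantitative trait loci (QTL) and expression QTL (eQTL) in multi-breed
    livestock populations. Simulates diploid dosage genotypes with tunable
    linkage disequilibrium and cross-breed divergence, trait deviations with
    sex-dependent accuracy, and negative-binomial RNA-seq counts with cis
    effects; fits mixed-model single-variant associations with a genomic
    relationship matrix and sample-size weighted z-score meta-analysis;
    estimates variant effects with a four-class normal-mixture Bayesian
    regression (Bayes R) by Gibbs sampling; maps QTL by the variance of local
    genomic estimated breeding values in 250 kb sliding windows; scans for
    cis-eQTL; correlates local breeding values with gene expression against a
    within-window permutation null; compares eQTL enrichment between top- and
    randomly-selected window sets; and computes per-variant colocalisation
    posterior probabilities from configuration-enumeration fine-mapping.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    tools,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
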