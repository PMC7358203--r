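Package: duet
Title: Joint Bayesian Analysis of Differential Expression and Differential
    Splicing from Isoform Counts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Hierarchical Bayesian analysis of isoform-level RNA-seq counts
    that detects differential gene expression (DGE) and differential
    alternative splicing/transcription (DAST) simultaneously. Gene expression
    is modelled on the log2 counts-per-million scale with per-observation
    variances taken from a mean-variance trend; isoform abundances are
    modelled as compositional fractions of the gene total, with case fractions
    linked to control fractions through an Aitchison perturbation on the
    simplex. Posterior probabilities of expression and splicing change are
    obtained by MCMC and turned into gene categories (DGE, DAST, DAST/DGE,
    static). The package also ships a negative-binomial isoform-count
    simulator with ground truth, an oracle t-statistic splicing baseline, and
    precision-recall evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    coda
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rjags,
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: RNASeq, AlternativeSplicing, DifferentialExpression,
    DifferentialSplicing, Bayesian, Transcriptomics
RoxygenNote: 7.3.3
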