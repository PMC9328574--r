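Package: DeepPRS
Title: Explainable Deep Transfer Learning for Polygenic Risk Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage framework for genomic risk prediction from dense
    genotype data. Stage one screens genes with a permutation-based
    group-wise feature importance score: a small multi-layer perceptron is
    fitted per gene and the loss difference between observed and
    subject-permuted genotypes, aggregated over K cross-validation folds,
    yields an asymptotic one-sided test of predictive importance. Stage two
    builds a transfer-learning prediction network that stacks new hidden
    layers on the frozen last hidden layers of the selected per-gene
    networks and adds a genomic best linear unbiased prediction (gBLUP)
    background node capturing infinitesimal additive effects. Includes
    readers for PLINK and VCF genotypes, gene-region grouping from BED/GFF3
    annotations, a synthetic genotype/phenotype simulator with within-gene
    linkage disequilibrium, and Monte-Carlo harnesses for type-I error and
    power evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    vcfR,
    data.table,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
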