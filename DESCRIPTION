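Package: portal5hmc
Title: Portal Venous Blood cfDNA 5hmC Liquid-Biopsy Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for cell-free DNA 5-hydroxymethylcytosine
    (5hmC-Seal) liquid-biopsy data from portal venous blood: building a
    hydroxymethylated-region (hMR) set from per-sample peaks, negative-binomial
    Wald tests for differentially hydroxymethylated regions (DhMRs),
    stability-consensus recursive feature elimination for marker-panel
    selection, penalized logistic classification with ROC validation, and
    downstream profiling (metagene gene-body coverage, genomic-feature
    annotation, PCA, correlation, Kaplan-Meier survival stratification).
    Includes a seeded synthetic-cohort generator with planted ground truth so
    the full pipeline runs and is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    survival,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    pROC,
    yaml
Config/testthat/edition: 3
biocViews: Epigenetics, DNAMethylation, DifferentialMethylation,
    Classification, Sequencing
RoxygenNote: 7.3.3
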