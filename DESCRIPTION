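Package: methylDMA
Title: Differential Methylation Analysis and Discriminant Profiling of
    Whole-Genome Bisulfite Methylomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pairwise differentially methylated position (DMP) calling from
    per-cytosine bisulfite count tables using Fisher's exact test with
    context-specific false discovery rate policies (Storey q-values for CG,
    a two-stage prefilter/FDR rule for CHG and CHH), annotation of DMPs to
    genes and transposons with normalized boundary-bin metaprofiles and
    chromosomal density tracks, group-wise differentially methylated region
    (DMR) detection by site clustering with pooled exact tests, and
    multivariate discrimination of samples from region methylation vectors
    (PCA, linear discriminant analysis, Ward clustering, Pillai's trace,
    SVM corroboration with repeated cross-validation). Includes a synthetic
    methylome generator that plants recorded differential-methylation truth
    for power and false-discovery evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
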