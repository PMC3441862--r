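Package: cnvIntegrate
Title: Integrative Copy-Number and Expression Analysis of Paired
    Tumor/Normal Arrays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end analysis of paired tumor/normal array-CGH and
    expression data for somatic copy-number studies: per-sample log2-ratio
    centralization and maximal-scoring-interval segmentation with
    aberration filters, genome-wide recurrence profiles and minimal common
    region discovery, Fisher exact region scans between clinical subtypes,
    gene-level copy-number dosage scoring (fold change and Pearson
    correlation), two-way average-linkage clustering, and 2^-ddCt qPCR
    relative quantification. Includes a seeded synthetic-cohort generator
    with known injected aberrations and dosage genes for calibration and
    parameter-recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    graphics,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
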