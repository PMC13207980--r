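Package: epientropy
Title: Epiallele Entropy Analysis for Whole-Genome Bisulfite Sequencing Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies DNA methylation stochasticity in population cohorts from
    per-read CpG methylation patterns (epireads). Tallies epialleles in sliding
    CpG windows, computes base-2 Shannon entropy normalized by window size, and
    decomposes pooled-group entropy into within- and between-individual
    components (a mutual-information decomposition). Includes coverage matching
    by group-minimum downsampling in fixed genomic bins, region-level ecotype
    comparisons with exact Wilcoxon rank-sum tests and quantile decomposition of
    entropy divergence, a C-to-T transition entropy control that separates
    genetic from epigenetic signal, integration of promoter entropy with
    expression variability and chromatin accessibility, and a Dirichlet-
    multinomial cohort simulator with ground-truth tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'epientropy-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'io.R'
    'entropy.R'
    'coverage.R'
    'simulate.R'
    'regions.R'
    'ctcontrol.R'
    'integration.R'
    'pipeline.R'
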