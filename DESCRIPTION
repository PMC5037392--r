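Package: PoolSeqFilter
Title: Objective Variant Filtering for Pooled Sequencing Experiments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating allele frequencies from pooled-sequencing
    (Pool-seq) read counts and for objectively selecting variant-filtering
    cut-offs. Spurious variants created by sequencing errors concentrate at
    low allele frequency and low caller quality; the package selects a
    Quality Filter (QF) and a Minimum-Percentage-of-reads Filter (MPF)
    threshold by minimising the two-sample Kolmogorov-Smirnov D statistic
    between the quality-score distributions of database-annotated and novel
    variants, intersects the two filters, and benchmarks filtered call sets
    against individual-sequencing truth sets. A fully parameterised
    synthetic-cohort generator with ground truth supports calibration and
    testing of the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
biocViews: Genetics, SNP, VariantDetection, Sequencing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
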