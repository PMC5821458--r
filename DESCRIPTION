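Package: grpause
Title: Pol II Pausing and Cistrome Analysis of Glucocorticoid-Repressed
    Inflammatory Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies signal-induced, glucocorticoid-repressed genes into
    RNA polymerase II promoter-proximally paused and non-paused classes from
    ChIP-seq coverage, and quantifies transcription-factor co-occupancy
    around them. Provides TMM-normalized differential gene-set derivation
    from RNA-seq counts with a common-dispersion negative-binomial exact
    test, a pausing-index statistic with strand-aware promoter and gene-body
    windows, replicate-union and Venn partitioning of peak sets, genomic
    feature annotation, class-conditional promoter-occupancy fractions with
    exact binomial intervals, and TSS-anchored metagene matrices and mean
    profiles. A seeded synthetic-data generator emits gene models, coverage
    tracks, peak sets and count matrices with ground-truth labels so every
    stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
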