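Package: txreorg
Title: Growth Fitness and Transcriptome Reorganization Analysis for Bacterial
    Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse bacterial growth fitness and transcriptome
    reorganization under genomic (genome reduction), environmental (chemical
    stressor) and evolutionary interruptions. Implements exponential growth
    rate extraction from OD600 time series by a windowed log-ratio rule,
    FPKM conversion and global log-scale normalization, chromosomal
    periodicity of gene expression on a circular genome (sliding-window
    spatial profile, periodogram, Fisher's g-test, least-squares periodic
    curve fit), transcriptome epistasis regression of simultaneous versus
    additive expression changes, Rank Product differential expression with
    permutation or exact null, binomial functional enrichment with Bonferroni
    correction, and weighted co-expression network modules (soft thresholding,
    topological overlap, adaptive tree cut, eigengene merging, trait
    correlation and module classification). A synthetic-data generator with
    known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'enrichment.R'
    'epistasis.R'
    'expression.R'
    'growth.R'
    'io.R'
    'network.R'
    'periodicity.R'
    'rankprod.R'
    'synthetic.R'
    'txreorg-package.R'
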