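Package: DendriteLoc
Title: Sub-Cellular RNA Localization Analysis for Paired Soma/Dendrite Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies dendritically localized RNAs from paired soma/dendrite
    RNA sequencing of single neurons. Builds union 3'UTR and 3'-isoform
    terminal-window quantification features from gene annotations, counts
    strand-specific reads, normalizes with median-of-ratios size factors, and
    calls gene-level (deDend), constitutive (consDend), and 3'UTR
    isoform-specific (isoDend) dendritic RNA sets using paired exact Wilcoxon
    signed-rank tests on dendritic read fractions and distal-fraction changes.
    Includes read-downsampling variability controls, length-matched background
    construction, G-quadruplex and position-weight-matrix motif scanning,
    single-exemplar covariance-model detection of B1/B2 SINE hairpins, study
    master-list integration, and a synthetic paired-compartment data generator
    with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, RNASeq, SingleCell, AlternativePolyadenylation,
    SequenceMatching
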