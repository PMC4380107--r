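Package: hmcprofiler
Title: 5-Hydroxymethylcytosine Promoter Profiling and Methylation
    Resistance Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for studying how
    5-hydroxymethylcytosine (5hmC) marking of gene promoters in normal
    tissue relates to DNA methylation change in matched tumours.
    Implements hmeDIP-seq coverage quantification (per-million
    normalisation, input subtraction, TSS metagene and feature
    distribution statistics), narrow/broad promoter profile ranking,
    CpG-island detection and promoter CpG-content classification,
    Infinium-style beta-value processing (probe filtering, peak-based
    type I/II correction, channel log-ratios with delta-method standard
    errors, weighted empirical-Bayes moderated differential
    methylation), and the cross-analyses that link them: 5hmC-high/low
    locus cross-tabulation, peak-to-promoter overlap depletion testing,
    and three-way bivalency Venn analysis. A fully deterministic
    synthetic cohort generator with planted ground truth makes every
    stage testable end to end.
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
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
biocViews: Epigenetics, DNAMethylation, Coverage, Sequencing,
    MethylationArray, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
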