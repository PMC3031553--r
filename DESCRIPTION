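Package: seasight
Title: Cross-Platform Integration of Sequencing and Microarray Expression Data
Version: 0.1.0
Authors@R: person("SeaSight", "Developers", email = "devel@seasight.example.org",
    role = c("aut", "cre"))
Description: Imports mapped sequencing reads (SAM/BAM/tabular), raw microarray
    probe intensities and genomic locus annotations (GFF3/PTT/tabular),
    reconciles them onto a common set of genomic features through a locus
    merging algebra (union, pairwise, greedy, minmax), quantifies read data
    (naive counts, coverage, RPKM, DCPM), and normalizes everything into one
    comparable expression matrix via a validated, state-typed
    transformation-matrix engine with background correction (subtraction,
    normexp), quantile/scaling/loess normalization, median-polish
    summarization, and generic value transforms.  Includes a seeded
    synthetic-study generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    BiocGenerics,
    rtracklayer,
    GenomicRanges,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
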