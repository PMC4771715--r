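Package: cotarget
Title: Direct Transcriptional Target Calling from Paired ChIP-seq and
    Knockdown RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates transcription-factor ChIP-seq with shRNA-knockdown
    RNA-seq to identify direct transcriptional targets of a factor pair
    (e.g. RUNX2/CBFB). Provides peak-intensity scoring from per-base tag
    coverage, two-factor co-occupancy analysis with Venn decomposition and
    rank correlation of matched peak intensities, strand-aware assignment of
    peaks to genes via promoter/gene-body/distal windows, a two-hairpin
    concordant knockdown filter on RPKM matrices, direct-target
    classification, hypergeometric gene-set enrichment, small ChIP-qPCR and
    cell-growth calculators, and seeded synthetic-data generators with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
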