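Package: smrnapipe
Title: Small-RNA Sequencing miRNA Quantification and Differential Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable re-implementation of a small-RNA sequencing analysis
    pipeline for mature microRNA profiling: read admission filtering (poly-A,
    ambiguous bases, 5' adapter carry-over, 3' adapter flank requirement),
    adapter trimming, collapsing of identical inserts into counted tags,
    exclusion of degraded-mRNA fragments against an exon database, assignment
    of tags to annotated mature miRNAs, a multi-mapping-corrected RPKM
    statistic C/(L*M*N)*1e9, and threshold-based two-condition differential
    calling with a signed fold-change convention. Ships a synthetic read
    simulator with ground truth for end-to-end validation, and the published
    differential miRNA tables of a cord-blood versus peripheral-blood
    endothelial progenitor cell comparison as a machine-readable fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
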