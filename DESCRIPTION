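Package: markconcord
Title: Replicate-Consistency Differential Peak Calling and
    Histone-Mark/Expression Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting stable histone-methylation changes from
    replicated ChIP-seq peak calls. Implements occupancy-based consensus
    peak construction across replicates, the stringent condition-exclusive
    differential criterion for broad marks (present in every replicate of
    one condition, absent from every replicate of the other),
    replicate-support histograms, a simple count-based differential test,
    strand-aware peak-to-gene annotation with TSS/promoter/gene-body
    classification, a two-mark by expression concordance matrix, and
    hypergeometric gene-set overlap testing. Includes a synthetic-data
    generator with planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
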