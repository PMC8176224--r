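Package: cernet
Title: Cross-Species Co-Differential Expression and ceRNA Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for inferring competing endogenous RNA (ceRNA) networks
    from cross-species whole-transcriptome expression data. Implements
    class-specific differential-expression filtering for mRNA, lncRNA,
    miRNA and circRNA, projection of one species' results onto another
    through a one-to-many ortholog map with direction-aware intersection,
    positional lncRNA-gene association rules (cis window, antisense
    overlap) plus a co-expression stand-in for trans relations,
    correlation-gated miRNA-target pairing, a hypergeometric test for
    shared miRNA sponges, Fisher over-representation analysis, and
    summary reporting. A synthetic-data generator with planted ground
    truth (differential transcripts, ceRNA triplets, ortholog
    multiplicity) supports end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
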