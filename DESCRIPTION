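Package: ripenrich
Title: Peak Calling and Enrichment Scoring for Bacterial RIP-seq with a Mock Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies RNAs co-immunoprecipitated with an RNA-binding
    protein from unstranded short-read coverage. Peaks are maximal runs of
    genomic positions at or above a read-depth threshold, scored by the
    ratio of RPKM (reads per kilobase per million mapped reads) between the
    immunoprecipitated and mock-control libraries, assigned a strand from a
    transcription start site table, and classified into functional
    categories (tRNA/rRNA, sRNA, 5' leader, and ORF subclasses). A
    synthetic-data module generates annotated toy genomes and matched
    IP/control read sets with known enriched regions so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
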