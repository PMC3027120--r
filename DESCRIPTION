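Package: seqsignal
Title: Gene Expression Scores, Signal Maps and Change-Point Detection
    from Short-Read Alignments
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes gene-level RPKM/FPKM expression scores from
    short-read alignments by combining exon-mapped reads (SAM/BAM) with
    exon-exon junction reads (BED), builds base-wise coverage signal
    maps and group-wise differential signal maps, exports
    UCSC-compatible wiggle tracks with configurable chromosome naming,
    produces alignment statistics reports (uniquely mapped and
    exonic/intronic/intergenic breakdowns), and detects mean/variance
    change points in differential signal maps over annotated intervals
    such as 3'-UTRs using a Schwarz-Information-Criterion model
    selection rule. Includes a deterministic synthetic-data generator
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicAlignments,
    Rsamtools,
    stats,
    tools,
    utils
Suggests:
    BiocGenerics,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
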