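Package: rsrun
Title: Read-Split-Run Discovery of Short Non-Canonical Splice Junctions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide discovery of short non-canonical splice junctions
    from RNA-Seq data by exhaustive splitting and re-alignment of unmapped
    reads. Unmapped reads are split into half-pairs at every admissible
    offset, re-aligned to the genome, assembled into matched pairs whose
    genomic gap falls within a candidate-distance window, clustered into
    junctions with a positional boundary buffer, filtered by supporting-read
    count, and compared between case and control samples so that junctions
    present only in the splicing-competent sample surface (the
    IRE1-alpha/Xbp1 26 nt cytoplasmic excision is the motivating positive
    control). Includes construction of an expanded genome of annotated
    exon-exon junction flanks for the first alignment pass, an ordinary
    least-squares model predicting junction counts from the pipeline's three
    key parameters, and a deterministic synthetic-data generator with
    machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    BiocGenerics,
    S4Vectors,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
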