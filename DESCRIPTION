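Package: circchar
Title: Characterization of Circular RNAs from Chimeric RNA-Seq Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-detection characterization of circular RNA (circRNA)
    candidates from chimerically mapped RNA-seq reads. Starting from
    back-splice junctions and their supporting read names, the package
    extracts per-circle alignment files, detects alternatively spliced
    (skipped) exons within circle boundaries, classifies read pairs into
    single- and double-breakpoint fragments as indirect evidence of
    circularity, summarizes circular isoforms per host gene, computes
    exon-wise and position-wise coverage profiles, and clusters
    length-normalized coverage profiles with correlation-distance K-means
    to surface likely false-positive circles. A seeded simulator of
    back-spliced paired-end reads with known truth supports testing end
    to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments,
    mclust,
    optparse
Config/testthat/edition: 3
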