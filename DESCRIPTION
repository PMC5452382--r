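Package: overlapviz
Title: Intersection and Visualization of Multiple Genomic Region and Name Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes intersections of two or more genomic region sets (BED,
    GFF/GTF, or VCF) or plain-text name lists, decomposes them into the
    2^n - 1 exclusive membership categories, derives pairwise overlap
    statistics (overlap counts, fractions of overlap, Jaccard statistics,
    Fisher's exact test against a genome background, and relative-distance
    distributions), and renders classical Venn diagrams (up to six sets),
    UpSet plots, and clustered pairwise heat maps. All figures are written in
    PDF, SVG, PNG, and TIFF together with the plain-text matrices (set
    columns, binary membership, pairwise matrix, overlap counts) used for
    downstream interactive exploration. A seeded synthetic-data generator
    provides region sets with analytically known expected overlap for
    self-contained testing, and a three-subcommand command-line interface
    (venn, upset, pairwise) exposes the full pipeline.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    jsonlite,
    GenomicRanges,
    IRanges
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
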