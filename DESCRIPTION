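Package: ncsplice
Title: Cataloging and Classification of Non-Canonical Splice Junctions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for non-canonical splice junctions called
    from spliced-aligner junction tables. Junctions are filtered by unique
    read support, strand-resolved, and categorized as canonical (GT-AG) or
    non-canonical from sense-strand terminal dinucleotides fetched from the
    genome. Non-canonical junctions are classified as U2/U12-like versus
    non-U2/U12-like by scoring 9-nt donor and 23-nt acceptor windows against
    position weight matrices trained on the sample's own canonical junctions,
    with a score threshold derived from a scrambled-sequence null
    distribution. Downstream summaries include 4x4 splice-site dinucleotide
    matrices with power-law heatmap normalization, and intron-length
    comparisons by two-sided Mann-Whitney U tests, ECDFs and boxplot
    statistics. A seeded synthetic-data generator emits a toy genome,
    annotation, junction table and ground truth so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
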