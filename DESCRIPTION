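Package: dsbtools
Title: Genomic Analysis of Double-Strand Break Fragility Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localising and characterising genomic double-strand
    break (DSB) regions from interval-based break maps. Provides BED-style
    interval algebra (merge, intersect, subtract, clamped extension, window
    tiling and UpSet-style window membership counts), per-chromosome
    permutation tests of region association (Z-score and empirical p) and
    sampled fold-change enrichment, scanners for simple tandem repeats,
    alternating purine-pyrimidine (Z-DNA-prone) runs and IUPAC consensus
    motifs, a windowed oxidative-damage enrichment score with low-coverage
    scaling and top-fraction selection, break-set classification across cell
    types, and seeded synthetic-data generators that make every stage
    verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    S4Vectors,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
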