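Package: quadtag
Title: Downstream Analysis of i-Motif and G-Quadruplex CUT&Tag Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable downstream pipeline for mapping i-motif (iM) and
    G-quadruplex (G4) DNA secondary structures from CUT&Tag data:
    SEACR-style signal-block peak calling with replicate consensus,
    quadruplex-motif prediction at three stringency levels with a
    shuffle-based enrichment null, genomic feature annotation with
    abundance-normalized distributions, TSS metaprofiles, quality-control
    metrics (RPGC coverage, FRiP, saturation and library-complexity
    curves), and integration of structure calls with expression
    quartiles. Ships a synthetic-data generator (genomes, planted motifs,
    enriched fragment sets, gene models, expression tables) so the whole
    pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
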