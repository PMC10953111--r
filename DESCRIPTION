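Package: nucposer
Title: Nucleosome Positioning and Histone-Mark Occupancy Analysis for Fungal Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds nucleosome maps from MNase-seq coverage with a differential-filter
    peak caller, detects +1/-1 nucleosomes and nucleosome-depleted regions (NDRs) at
    gene starts with bidirectional-promoter flagging, calls per-gene promoter occupancy
    of the histone variant H2A.Z and of H3K4me3/H3K27me3 from replicate ChIP coverage
    using CPM thresholds in strand-aware ATG windows, and integrates the chromatin
    calls with expression (log2 RPKM, differential-expression classes), co-occupancy
    summaries, +1-anchored enrichment matrices and BLAST-based conservation classes.
    Includes a seed-reproducible synthetic-data generator (annotation, chromatin truth,
    MNase fragments, replicate ChIP tracks, expression tables) for end-to-end recovery
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
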