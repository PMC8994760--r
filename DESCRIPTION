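Package: herbaudit
Title: Multi-Barcode Metabarcoding Audit of Herbal Mixture Composition
Version: 0.1.0
Authors@R:
    person("Herbaudit", "Developers", email = "herbaudit@example.org",
           role = c("aut", "cre"))
Description: Audits the biological composition of multi-ingredient herbal
    preparations from ITS2 and trnL amplicon sequencing. Provides
    prescription-aware species classification (prescribed, substituted,
    contaminated herbal species), MID demultiplexing and per-barcode read
    quality control, a prescribed-species-preferred taxonomic assignment
    rule for tabular alignment hits, relative-abundance threshold
    filtering and rarefaction, detection sensitivity of prescribed herbal
    materials with multi-barcode unions, presence-based sample similarity
    (Euclidean distance, hierarchical clustering, distance-cutoff
    networks, PCA), and manufacturer-discriminating marker selection with
    an abundance-ratio (MEI) score evaluated by ROC analysis. A seeded
    synthetic-data generator (reference databases, reads, alignment-hit
    tables with ground-truth manifests) makes every stage testable
    without external sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    ape,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
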