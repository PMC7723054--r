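Package: stemlooplib
Title: Terminal Stem-Loop Extraction and Barcoded RNA Structure Library Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-silico pipeline for profiling folded RNA elements with a
    barcoded structure library. Parses RNA secondary structures in dot-bracket
    and CT formats into pair tables and loop-decomposition trees, extracts
    single- and multi-terminal stem-loop motifs and pre-miRNA terminal loops,
    designs synthesis-ready barcoded oligo probe libraries (25-nt barcodes,
    18-bp stabilizing stems, T7 promoter templates), converts spot-level
    microarray fluorescence into per-structure binding intensities with
    Z-scores and top-fraction selections, and interprets binding profiles via
    k-mer relative-frequency enrichment, position frequency matrices,
    structural-context motif analysis, and G-quadruplex G-tract scanning. A
    synthetic-data module generates every input class (structures,
    miRBase-like hairpin records, orthogonal barcode pools, simulated
    two-channel fluorescence experiments with planted binders) so the whole
    system is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'structure-model.R'
    'motif-extraction.R'
    'premirna.R'
    'library-design.R'
    'quantification.R'
    'enrichment.R'
    'synthetic-data.R'
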