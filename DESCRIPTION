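Package: chimeradose
Title: Read-Depth Dosage Analysis of Periclinal Chimeras in Polyploid Mutant Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects megabase-scale deletions and insertions from binned
    whole-genome sequencing coverage and classifies the meristematic cell
    layer (L1 epidermis versus inner L2/L3) in which each event arose, using
    a cell-layer mixture model of normalized read dosage. Includes a
    population simulator for irradiated clonal mutant collections with
    haplotype-resolved scaffolds, control-normalized dosage profiling,
    run-based indel segmentation with gap bridging and flank extension,
    leaf/root layer corroboration, population summary tables (dose response,
    layer bias, breakpoint density, shared deletions, gene overlap), and
    essential-oil chemotype fold-change and correlation summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
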