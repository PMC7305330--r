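Package: trampcrac
Title: Substrate-Specificity Mapping of Yeast TRAMP Complexes from CRAC,
    RNAseq and Pull-Down Proteomics Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for the computational analyses used to map
    the RNA substrate specificity of the Saccharomyces cerevisiae TRAMP
    (Trf4/5-Air1/2-Mtr4) complexes from UV crosslinking (CRAC), RNAseq and
    label-free pull-down proteomics data. Covers read pre-processing
    (barcode-aware PCR-duplicate collapsing, low-complexity filtering,
    non-templated oligo(A)-tail identification), transcript-class
    quantification with RPM/RPKM normalisation, co-targeting and
    co-localization correlation matrices, TSS- and pA-anchored metagene
    profiles, a run-length peak caller with peak-anchored cross-factor
    alignment, five-bin occupancy k-medians clustering, stratified
    differential fold-change analysis, and iBAQ/riBAQ pull-down enrichment
    with TRAMP complex stoichiometry inference. A seed-deterministic
    synthetic-data module generates toy genomes, annotations, CRAC/RNAseq
    reads and iBAQ tables with complete truth tables so every analysis can
    be exercised end-to-end against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
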