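Package: c4kit
Title: Comparative Genomics and Physiology Toolkit for C3/C4 Grass Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational companion for draft-genome studies of C3 grasses
    embedded in C4 clades. Implements chloroplast-genome finishing by exact
    20-mer seed-and-extend read matching with quadripartite (LSC/IRb/SSC/IRa)
    structure detection and k-mer coverage QC; k-mer multiplicity histograms
    and genome-size / single-copy-fraction estimation; a leaf
    developmental-gradient expression pipeline (FPKM, expressed-gene
    filtering, correlation, hierarchical clustering, cross-species segment
    matching); a three-stage comparative screen for C4-divergent
    transcription factors with lineage classification; diagnostic
    amino-acid-residue scanning in protein alignments (e.g. PEPC A780S); and
    C3/C4 A-Ci photosynthesis model curves with compensation-point
    computation. Ships synthetic-data generators with planted ground truth so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
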