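Package: crisprworm
Title: Guide RNA Selection and Knockout Quality Control for CRISPR/Cas9
    Engineering in C. elegans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for engineering targeted gene deletions in
    Caenorhabditis elegans with CRISPR/Cas9.  Enumerates every SpCas9
    (NGG) guide RNA candidate in a genome and applies a conservative
    filter cascade (GC content, poly-T tracts, seed k-mer uniqueness,
    genome-wide off-target search at edit distance three, RNA folding
    energy, cut-site feature annotation); designs homology arms and
    dual-marker repair templates for homology-directed repair
    deletions; classifies edited strains from a four-reaction PCR
    panel; and screens whole-genome sequencing call tables for
    off-target variants and copy-number changes against the parental
    strain.  A deterministic simulator generates genomes, gene models,
    edit outcomes, variant cohorts and coverage tracks with ground
    truth for testing the full pipeline without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    optparse,
    withr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
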