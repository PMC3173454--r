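Package: bacmapr
Title: BAC Physical Map Construction, Genetic Anchoring and Synteny Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for building and exploiting BAC-based physical maps from
    high-information-content fingerprints (HICF). Provides a seeded simulator
    of genomes, partial-digest BAC libraries and multi-enzyme fingerprints;
    Sulston-score overlap testing with tolerance band matching; FPC-style
    contig assembly with consensus-band (CB) layout, Q-clone detection (DQer)
    and relaxed end merging; three-dimensional pooled overgo hybridization
    design and deconvolution for genetic-marker anchoring; pseudomolecule
    construction with CMAP and AGP export; dense minimum-tile-path selection
    for BAC-end sequencing; and collinear anchor chaining into synteny blocks
    with coverage statistics and linkage-group prediction for unanchored
    contigs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    IRanges,
    S4Vectors,
    BiocGenerics,
    Biostrings,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
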