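Package: mitograph
Title: Graph-Based Reconstruction of Recombining Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts a fragmented short-read assembly of a plant
    mitochondrial genome into an undirected terminus graph built from exact
    contig end overlaps, identifies recombinogenic repeat pairs embedded in
    "double forks", quantifies the stoichiometry of all four
    contig-repeat-contig junction variants per repeat from mate-pair and
    long-read placements, and enumerates and reconstructs all master- and
    sub-circle genome configurations by budgeted closed-walk traversal.
    Includes a synthetic generator that plants circular genomes with direct
    and inverted repeat pairs, fragments them into overlapping contigs with
    coverage tiers, and simulates spanning reads, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
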