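Package: jplacer
Title: Read, Validate and Manipulate Phylogenetic Placement (jplace) Files
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A toolkit for the jplace (JSON placement) file format used to
    store phylogenetic placements of query sequences on a fixed reference
    tree. Parses and writes the edge-numbered Newick dialect (curly-brace
    edge numbers, square-bracket edge comments), models the full jplace
    version 3 document, performs semantic validation, and implements the
    manipulations the format is designed for: subsetting and merging
    placement collections, best-placement extraction under likelihood
    weight ratio, posterior probability or parsimony criteria,
    multiplicity accounting, relational (two-table) export, canonical
    post-order edge renumbering, and grafting of placements as pendant
    branches onto the reference tree. Includes a seeded synthetic
    document generator for property testing and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
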