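Package: ccatlas
Title: Knobs-into-Holes Detection and Atlas Classification of Coiled Coils
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects knobs-into-holes (KIH) side-chain packing between
    alpha-helices in protein structures (PDB and mmCIF), builds the directed
    helix-interaction multigraph under a distance cutoff (scut) and a
    per-pair interaction-count cutoff (kcut), and names every connected
    component of the simplified graph by isomorphism against an internally
    enumerated Atlas of all 1253 simple graphs on at most seven nodes,
    extending the catalogue with "U" names for larger graphs as they are
    encountered. Alpha-helical barrels are recognised as cyclic graphs.
    Includes exact Polya (cycle-index) counting of graph isomorphism
    classes, and a generator of ideal synthetic helix bundles with
    prescribed interaction topology for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
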