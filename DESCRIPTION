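Package: yana
Title: Yeast Augmented Network Analysis for Cross-Species Modifier Discovery
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for yeast-augmented network analysis of human
    disease genes: calls genetic-modifier hits (synthetic lethal and synthetic
    suppressor) from colony-size grids of a fission-yeast synthetic genetic
    array screen, maps hits to human orthologs by consensus over curated
    tables, builds confidence-thresholded protein-interaction subnetworks in
    both species, augments the yeast network with first-degree neighbors and
    an orphan-rescue rule, and nominates therapeutic-target candidates by
    cross-species network overlap. Includes seeded generators for every input
    (colony grids with plate effects and spatial gradients, random PPI edge
    lists, ortholog tables, embryo phenotype scores) so the whole pipeline is
    testable without external downloads, plus summary statistics for
    categorical motor-axon severity phenotypes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
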