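Package: PhyloTurnover
Title: Phylogenetic and Taxonomic Beta Diversity of Tree Communities with
    Null Models, Spatial Eigenfunctions and Variance Partitioning
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify taxonomic and phylogenetic beta diversity of
    forest plot networks and to attribute it to environmental and dispersal
    filters. Implements Sorensen and PhyloSorensen dissimilarities with their
    turnover and nestedness components, richness-preserving and tip-shuffling
    null models with standardized effect sizes (beta NRI and beta NTI),
    principal coordinates of neighbour matrices (PCNM) spatial eigenfunctions
    with scale classification, distance-based redundancy analysis with
    permutation tests and forward selection under a double stopping rule, and
    variance partitioning across climate, soil, geomorphology and space.
    Includes a metacommunity simulator with known environmental-filtering and
    dispersal-limitation strengths for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    vegan,
    Matrix,
    jsonlite
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
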