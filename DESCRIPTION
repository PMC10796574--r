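Package: treeconv
Title: Convergence Scenarios on Equidistant Phylogenetic Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for a distance-based model of convergent evolution on
    rooted binary equidistant (molecular-clock) phylogenetic trees. A
    convergence scenario places two equal-length, disjoint converging paths
    on the tree, spanning heights alpha to beta, with strength epsilon; the
    induced dissimilarity subtracts 2*epsilon*(beta - h_R(x,y)) from the
    tree distance of every leaf pair split across the two paths. The package
    constructs and validates scenarios, computes the modified dissimilarity,
    evaluates closed-form thresholds deciding whether it is a distance, a
    triplet-respecting distance, a metric, a tree metric or an ultrametric,
    cross-checks every verdict against brute-force axiom oracles, recovers
    the tree topology from rooted triplets via the Build (Aho) algorithm,
    decides whether the tree height is identifiable from the dissimilarity,
    and constructs explicit confounding scenarios when it is not. Includes
    seeded generators for random generic equidistant trees and scenarios,
    plus readers and writers for Newick, square PHYLIP, TSV and JSON
    scenario files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
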