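Package: blueberrymap
Title: Quantifying Invasive Blueberry Spread from Annotated UAV Orthomosaics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Workflow for characterising an invasive highbush blueberry
    (Vaccinium corymbosum x angustifolium) incursion in wetlands from
    annotated UAV orthomosaics: per-bush allometry (connected-component
    counts, areas in m2, DEM-based maximum and median heights), spatial
    spread metrics (single-linkage distance clustering, quartic kernel
    density, Getis-Ord Gi* hotspots, and 0-dimensional persistent homology
    of annotated regions), and an imbalance-aware multi-label patch
    classifier with coarse-to-fine mask refinement evaluated by TPR,
    accuracy, Dice and ground-truth cover. A seeded synthetic wetland scene
    generator with full ground truth makes every stage testable without
    field imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    igraph,
    jsonlite,
    png,
    data.table,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
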