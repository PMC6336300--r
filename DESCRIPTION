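Package: stemscan
Title: Single-Scan Terrestrial Laser Scanning of Plantation Plots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processing pipeline for single-scan terrestrial laser scanner
    (TLS) data in small plantation plots: converts raw polar scan records
    (range, intensity, vertical and horizontal angle) into Cartesian point
    clouds and cylindrical range/intensity maps, detects tree trunks by
    clustering a breast-height transect with an angular-adjacency distance
    rule, fits stem circles by the Pratt and Taubin algebraic methods and
    Gauss-Newton geometric refinement, fits per-tree local ground planes with
    RANSAC, and estimates diameter at breast height (DBH), total tree height
    (via a k-nearest-neighbour outlier filter at the tree top) and stem
    position. Includes a seeded scan simulator that emulates the instrument's
    angular lattice, range noise and first-return occlusion over synthetic
    plantation plots with known ground truth, plus evaluation statistics
    (detection bookkeeping, bias and RMSE against reference tables) and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
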