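Package: scnvdp
Title: Dynamic-Programming Copy-Number Segmentation for Single-Cell DNA
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects shared copy-number turning points in single-cell
    whole-genome sequencing data by exact dynamic-programming optimisation
    of a simplified modified Bayesian information criterion over per-cell
    binned read depth. Takes matched raw and normalised cell-by-bin count
    matrices (dense TSV or MatrixMarket sparse, with BED bin annotations),
    finds the optimal segmentation of each chromosome, backtracks turning
    points, and calls an integer copy number per cell per segment. Includes
    a rank-one baseline normaliser, a clone-structured count simulator for
    validation, and evaluation utilities (turning-point precision/recall,
    Pearson/RMSE agreement, hierarchical clustering with ARI/NMI/Jaccard
    indices, and Gini-coefficient aneuploidy flagging).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    igraph,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
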