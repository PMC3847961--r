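Package: clrnet
Title: Genome-Scale Gene Network Inference with Association-Based CLR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale reverse engineering of gene association networks from
    normalized expression compendia. Extends the context likelihood of
    relatedness (CLR) background correction beyond mutual information to a
    menu of seven pairwise association estimators (Pearson, Spearman, Kendall
    tau-b, a bounded Theil-Sen score, weighted rank correlation, binned mutual
    information, and the maximal information coefficient), converts the
    corrected scores into pair-level z-scores, and thresholds them into
    Cytoscape-compatible edge lists. Includes a deterministic balanced
    pair-partition plan so parallel execution is bit-reproducible, seed-based
    subnetwork extraction (neighborhood expansion and cohesive greedy growth),
    a synthetic regulatory-topology expression simulator for benchmarking, and
    ROC/AUC plus sensitivity/specificity/accuracy evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    parallel,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
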