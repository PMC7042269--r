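Package: switchnet
Title: Switch-Gene Discovery in Hard-Thresholded Gene Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies "switch genes" -- network hubs that are on average
    anti-correlated with their co-expression partners, interact mostly outside
    their own module, and are not local hubs -- from case/control expression
    studies. Implements the full pipeline: per-gene linear models with
    empirical-Bayes variance moderation and Benjamini-Hochberg FDR control;
    hard-thresholded signed Pearson correlation networks with percentile,
    scale-free-fit and connectivity-based threshold selection; k-means module
    detection under the 1-minus-correlation distance with module eigengenes and
    memberships; date/party/fight-club hub cartography (APCC, within-module
    degree z, clusterphobic coefficient K) with role regions and switch-gene
    extraction; degree-preserving edge-shuffle, gene-set-overlap and
    neighbor-shuffle randomization nulls; targeted node-removal robustness
    curves; interactome proximity and separation statistics with degree-matched
    nulls; ROC/AUC evaluation; and a synthetic-data generator that plants
    recoverable modules, differential expression and switch genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    mclust,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    limma,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
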