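Package: multiroot
Title: Rooting Species Trees from Multi-Copy Gene Family Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Roots an unrooted species tree using multi-copy gene family
    trees that disagree with the species tree because of gene duplication
    and loss (GDL) and incomplete lineage sorting (ILS). Gene family trees
    are first rooted and tagged by duplication/loss parsimony and
    decomposed at duplication nodes into single-copy (ortholog) trees;
    the species tree is then rooted by scoring every candidate root edge
    against the empirical quintet topology frequencies of the single-copy
    trees, using inequalities and invariants of quintet topology
    probabilities under the multispecies coalescent. Includes the
    normalized clade distance for evaluating rooted trees, and a
    desk-scale simulator of species trees, duplication-loss locus trees,
    coalescent gene trees and topological gene-tree estimation error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    phytools,
    Rcpp,
    dplyr,
    tibble,
    purrr,
    rlang,
    yaml,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
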