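# Tree-comparison metrics: Robinson-Foulds on unrooted trees, the
# normalized clade distance (nCD) for rooted trees, and the root
# distance. For two rootings of the same unrooted topology the clade
# symmetric difference equals exactly twice the number of edges between
# the two root positions, so nCD = 2 * root_distance / (2n - 4).

check_same_leaves <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label)) {
    abort("trees have different leaf sets")
  }
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' Size of the symmetric difference of the nontrivial bipartition sets;
#' `normalized_rf()` divides by `2(n - 3)`, the maximum for binary
#' trees.
#'
#' @param a,b `phylo` objects on the same leaf set (`n >= 4`); rooted
#'   inputs are compared as unrooted topologies.
#' @return `rf_distance()`: a non-negative even integer;
#'   `normalized_rf()`: a value in `[0, 1]`.
#' @export
rf_distance <- function(a, b) {
  check_same_leaves(a, b)
  if (n_tips(a) < 4) abort("need at least 4 leaves")
  sa <- tree_split_keys(a)
  sb <- tree_split_keys(b)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

#' @rdname rf_distance
#' @export
normalized_rf <- function(a, b) {
  rf_distance(a, b) / (2 * (n_tips(a) - 3))
}

# canonical id of the edge a rooted tree is rooted on, in its unrooted
# topology
root_edge_of <- function(tree) {
  nt <- n_tips(tree)
  root <- nt + 1L
  ch <- tree$edge[tree$edge[, 1] == root, 2][1]
  below <- edge_node_tip_sets(tree)
  edge_id(below[[ch]], tree$tip.label)
}

# number of edges between two edges of an unrooted tree (0 if equal,
# 1 if adjacent); breadth-first search on the edge adjacency graph
edge_path_distance <- function(tree, id1, id2) {
  if (id1 == id2) return(0L)
  sets <- edge_tip_sets(tree)
  ids <- vapply(sets, edge_id, character(1), all_labels = tree$tip.label)
  e1 <- match(id1, ids); e2 <- match(id2, ids)
  if (is.na(e1) || is.na(e2)) abort("edge not found in tree")
  adj <- lapply(seq_len(nrow(tree$edge)), function(k) {
    which(tree$edge[, 1] %in% tree$edge[k, ] |
            tree$edge[, 2] %in% tree$edge[k, ])
  })
  dist <- rep(NA_integer_, nrow(tree$edge))
  dist[e1] <- 0L
  frontier <- e1
  while (length(frontier)) {
    nxt <- integer(0)
    for (f in frontier) {
      for (g in adj[[f]]) {
        if (is.na(dist[g])) { dist[g] <- dist[f] + 1L; nxt <- c(nxt, g) }
      }
    }
    if (!is.na(dist[e2])) return(dist[e2])
    frontier <- nxt
  }
  abort("internal error: disconnected edge graph")
}

#' Normalized clade distance between two rooted trees
#'
#' The symmetric difference of the proper nontrivial clade sets,
#' divided by `2n - 4` (its maximum for binary trees), so identical
#' rooted trees score 0 and maximally different rootings score 1. When
#' the two trees share an unrooted topology the root distance (number
#' of edges between the two root positions) is also reported, and the
#' clade symmetric difference equals twice the root distance.
#'
#' @param true_tree,est_tree Rooted `phylo` objects on the same leaf
#'   set, `n >= 3`.
#' @return A one-row tibble: `ncd`, `clade_symdiff`, `root_distance`
#'   (`NA` when the unrooted topologies differ), `n`.
#' @export
#' @examples
#' a <- parse_newick("((((a,b),c),d),e);")
#' b <- parse_newick("(((a,b),c),(d,e));")
#' ncd(a, b)
ncd <- function(true_tree, est_tree) {
  if (!ape::is.rooted(true_tree) || !ape::is.rooted(est_tree)) {
    abort("both trees must be rooted")
  }
  check_same_leaves(true_tree, est_tree)
  n <- n_tips(true_tree)
  ca <- names(tree_clades(true_tree))
  cb <- names(tree_clades(est_tree))
  sd <- length(setdiff(ca, cb)) + length(setdiff(cb, ca))
  same_topology <- n >= 4 &&
    rf_distance(ape::unroot(true_tree), ape::unroot(est_tree)) == 0
  rd <- NA_integer_
  if (same_topology) {
    u <- ape::unroot(true_tree)
    rd <- edge_path_distance(u, root_edge_of(true_tree),
                             root_edge_of(est_tree))
    if (sd != 2L * rd) {
      warn("clade symmetric difference is not twice the root distance")
    }
  }
  tibble::tibble(ncd = sd / (2 * n - 4), clade_symdiff = sd,
                 root_distance = rd, n = n)
}

#' Expected nCD of a uniformly random rooting
#'
#' Exact mean of [ncd()] between `true_tree` and the rooting of its own
#' unrooted topology on each of the `2n - 3` edges -- the error a
#' rooting method must beat to be better than chance.
#'
#' @param true_tree Rooted binary `phylo`.
#' @return A single number in `[0, 1]`.
#' @export
expected_random_ncd <- function(true_tree) {
  u <- ape::unroot(true_tree)
  er <- enumerate_rootings(u)
  mean(vapply(er$tree, function(t) ncd(true_tree, t)$ncd, numeric(1)))
}

#' Evaluate a rooting score table against the true rooted tree
#'
#' Reports the rooting error of the selected (rank-1) edge and the nCD
#' at every rank, a diagnostic curve showing how well the score orders
#' the candidate edges.
#'
#' @param table A `rooting_score_table` from [score_rootings()] or
#'   [disco_qr()].
#' @param true_tree The true rooted species tree.
#' @return An object of class `rooting_evaluation`: `report` (the
#'   rank-1 [ncd()] row) and `curve` (tibble: rank, edge_id, score,
#'   ncd, root_distance).
#' @export
evaluate_rooting <- function(table, true_tree) {
  stopifnot(inherits(table, "rooting_score_table"))
  u <- table$species_tree
  check_same_leaves(u, true_tree)
  rows <- table$table
  res <- lapply(seq_len(nrow(rows)), function(i) {
    r <- ncd(true_tree, root_at_edge(u, rows$edge_id[i]))
    cbind(rows[i, c("rank", "edge_id", "score")], r)
  })
  curve <- dplyr::bind_rows(res)
  curve <- curve[order(curve$rank), ]
  structure(list(report = curve[curve$rank == 1,
                                c("ncd", "clade_symdiff", "root_distance", "n")],
                 curve = tibble::as_tibble(curve)),
            class = "rooting_evaluation")
}

#' @export
print.rooting_evaluation <- function(x, ...) {
  cat("Rooting evaluation: rank-1 nCD =", round(x$report$ncd, 4),
      " root distance =", x$report$root_distance, "\n")
  invisible(x)
}

#' @export
tidy.rooting_evaluation <- function(x, ...) x$curve

#' @export
glance.rooting_evaluation <- function(x, ...) tibble::as_tibble(x$report)

#' @export
autoplot.rooting_evaluation <- function(object, ...) {
  d <- object$curve
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$ncd)) +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(color = .data$rank == 1), size = 2) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40",
                                           `TRUE` = "firebrick"),
                                guide = "none") +
    ggplot2::labs(x = "score rank", y = "nCD vs true rooting",
                  title = "Rooting error by score rank") +
    ggplot2::theme_minimal()
}
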