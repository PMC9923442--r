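# The quintet-rooting stage: sample quintets of species, estimate their
# unrooted topology distributions from single-copy gene trees, and score
# every candidate root edge of the species tree.

#' Choose the quintets used to root a species tree
#'
#' @param tree Unrooted binary species tree (`phylo`, `n >= 5`).
#' @param mode `"exhaustive"` scores all `choose(n, 5)` quintets;
#'   `"linear"` maps each of the `n - 3` internal edges to one quintet
#'   (the lexicographically smallest leaf in each of the four subtrees
#'   hanging off the edge, plus the smallest unused leaf from the
#'   largest of those subtrees); `"random"` draws `k` distinct quintets
#'   uniformly.
#' @param k Number of quintets for `mode = "random"`.
#' @param seed Optional integer seed for `mode = "random"`.
#' @return An object of class `sampling_plan`: a tibble with a `quintet`
#'   list-column (sorted character vectors of 5 species) and, in linear
#'   mode, the `edge_id` each quintet encodes.
#' @export
sample_quintets <- function(tree, mode = c("linear", "exhaustive", "random"),
                            k = NULL, seed = NULL) {
  mode <- match.arg(mode)
  n <- n_tips(tree)
  if (n < 5) abort("rooting requires at least five taxa")
  if (ape::is.rooted(tree)) abort("species tree must be unrooted")
  if (!ape::is.binary(tree)) abort("species tree must be binary")
  labels <- sort(tree$tip.label)
  if (mode == "exhaustive") {
    q <- utils::combn(labels, 5, simplify = FALSE)
    plan <- tibble::tibble(quintet = q, edge_id = NA_character_)
  } else if (mode == "random") {
    if (is.null(k) || k < 1) abort("mode = 'random' needs k >= 1")
    if (!is.null(seed)) set.seed(seed)
    seen <- character(0); q <- list()
    while (length(q) < min(k, choose(n, 5))) {
      cand <- sort(sample(labels, 5))
      key <- paste(cand, collapse = "|")
      if (!key %in% seen) { seen <- c(seen, key); q[[length(q) + 1L]] <- cand }
    }
    plan <- tibble::tibble(quintet = q, edge_id = NA_character_)
  } else {
    plan <- linear_encoding_plan(tree)
  }
  structure(plan, class = c("sampling_plan", class(plan)),
            mode = mode, seed = seed)
}

# one quintet per internal edge: smallest leaf of each of the four
# subtrees around the edge, plus the smallest unused leaf of the
# largest subtree (ties: lexicographically smallest representative)
linear_encoding_plan <- function(tree) {
  nt <- n_tips(tree)
  root <- nt + 1L
  parent <- rep(NA_integer_, nt + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  kids <- vector("list", nt + tree$Nnode)
  for (r in seq_len(nrow(tree$edge))) {
    kids[[tree$edge[r, 1]]] <- c(kids[[tree$edge[r, 1]]], tree$edge[r, 2])
  }
  below <- edge_node_tip_sets(tree)
  all_l <- tree$tip.label
  internal <- which(tree$edge[, 1] > nt & tree$edge[, 2] > nt)
  rows <- list()
  for (r in internal) {
    u <- tree$edge[r, 1]; v <- tree$edge[r, 2]
    sets <- lapply(kids[[v]], function(c) below[[c]])
    others <- setdiff(kids[[u]], v)
    sets <- c(sets, lapply(others, function(c) below[[c]]))
    if (!is.na(parent[u])) {
      sets <- c(sets, list(setdiff(all_l, below[[u]])))
    }
    stopifnot(length(sets) == 4)
    reps <- vapply(sets, min, character(1))
    sizes <- vapply(sets, length, integer(1))
    big <- order(-sizes, reps)[1]
    extra <- setdiff(sort(sets[[big]]), reps)[1]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      quintet = list(sort(c(reps, extra))),
      edge_id = edge_id(below[[v]], all_l))
  }
  dplyr::bind_rows(rows)
}

# tip labels below every node (list indexed by node number)
edge_node_tip_sets <- function(tree) {
  nt <- n_tips(tree)
  below <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) below[[i]] <- tree$tip.label[i]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1]; ch <- ord$edge[k, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below
}

# ---------------------------------------------------------------------------
# split pre-computation for fast quintet counting. With at most 30
# species, splits are integer bit masks over the sorted species
# universe; otherwise character sets are used.

prepare_gene_splits <- function(trees, universe) {
  universe <- sort(universe)
  fast <- length(universe) <= 30
  prep <- lapply(trees, function(tr) {
    nt <- n_tips(tr)
    sets <- edge_tip_sets(tr)
    sizes <- vapply(sets, length, integer(1))
    sets <- sets[sizes >= 2 & sizes <= nt - 2]
    if (fast) {
      pos <- match(tr$tip.label, universe)
      msk <- vapply(sets, function(s) {
        mask32_of(pos[match(s, tr$tip.label)])
      }, integer(1))
      list(present = mask32_of(pos), splits = unique(msk))
    } else {
      list(present = tr$tip.label, splits = unique(lapply(sets, sort)))
    }
  })
  structure(list(trees = prep, universe = universe, fast = fast),
            class = "gene_splits")
}

mask32_of <- function(positions) {
  sum(bitwShiftL(1L, positions - 1L))
}

# counts over the 15 topologies of catalog for quintet q (sorted)
quintet_counts <- function(prep, q, catalog) {
  counts <- integer(15)
  m <- 0L
  if (prep$fast) {
    qpos <- match(q, prep$universe)
    qbits <- bitwShiftL(1L, qpos - 1L)
    qmask <- sum(qbits)
    for (g in prep$trees) {
      if (bitwAnd(g$present, qmask) != qmask) next
      masked <- bitwAnd(g$splits, qmask)
      pc <- popcount(masked)
      pairs <- unique(c(masked[pc == 2L],
                        bitwAnd(qmask, bitwNot(masked[pc == 3L]))))
      if (length(pairs) != 2) next  # unresolved restriction
      loc <- vapply(pairs, function(p) {
        mask_of(which(bitwAnd(p, qbits) > 0L))
      }, integer(1))
      idx <- catalog$pair_index[min(loc) + 1L, max(loc) + 1L]
      if (idx >= 0) { counts[idx + 1L] <- counts[idx + 1L] + 1L; m <- m + 1L }
    }
  } else {
    for (g in prep$trees) {
      if (!all(q %in% g$present)) next
      inter <- lapply(g$splits, intersect, q)
      sz <- vapply(inter, length, integer(1))
      pairs <- unique(c(inter[sz == 2L],
                        lapply(inter[sz == 3L], function(s) setdiff(q, s))))
      pairs <- unique(lapply(pairs, sort))
      if (length(pairs) != 2) next
      loc <- vapply(pairs, function(p) mask_of(match(p, q)), integer(1))
      idx <- catalog$pair_index[min(loc) + 1L, max(loc) + 1L]
      if (idx >= 0) { counts[idx + 1L] <- counts[idx + 1L] + 1L; m <- m + 1L }
    }
  }
  counts
}

#' Empirical quintet topology distribution from single-copy gene trees
#'
#' For every gene tree containing all five species, the induced quintet
#' topology is read off the gene tree's splits; unresolved restrictions
#' (polytomies touching the quintet) are discarded. Support `m` counts
#' the gene trees that contributed.
#'
#' @param gene_trees List of single-copy `phylo` objects (species
#'   labels at the leaves; missing species are fine).
#' @param species Character vector of 5 species.
#' @return A [quintet_distribution()].
#' @export
estimate_quintet_distribution <- function(gene_trees, species) {
  if (length(species) != 5 || anyDuplicated(species)) {
    abort("need 5 distinct species")
  }
  q <- sort(species)
  universe <- sort(unique(c(q, unlist(lapply(gene_trees,
                                             function(t) t$tip.label)))))
  prep <- prepare_gene_splits(gene_trees, universe)
  quintet_distribution(quintet_counts(prep, q, quintet_catalog(q)), q)
}

# ---------------------------------------------------------------------------

#' Score all rootings of a species tree against single-copy gene trees
#'
#' For each sampled quintet with positive support, the cost of each of
#' the seven rootings of the species tree's induced quintet topology is
#' computed once against the quintet's empirical topology distribution
#' ([rooting_cost()]). The score of each of the `2n - 3` candidate root
#' edges is the sum, over quintets, of the cost of the rooted quintet
#' that rooting induces; the edge with the minimum score is selected
#' (exact ties broken by smallest canonical edge id and reported).
#'
#' @param species_tree Unrooted binary `phylo` on `n >= 5` species.
#' @param gene_trees List of single-copy `phylo` objects.
#' @param plan A [sample_quintets()] plan (default: linear encoding).
#' @return An object of class `rooting_score_table`: `table` (tibble
#'   with `edge_id`, `score`, `rank`, `n_informative_quintets`, `tied`),
#'   `root_edge`, `rooted_tree`, `counters` (operation counts backing
#'   the complexity contract), and per-quintet support.
#' @export
score_rootings <- function(species_tree, gene_trees,
                           plan = sample_quintets(species_tree)) {
  n <- n_tips(species_tree)
  if (n < 5) abort("rooting requires at least five taxa")
  if (ape::is.rooted(species_tree)) {
    abort("species tree must be unrooted")
  }
  if (!ape::is.binary(species_tree)) abort("species tree must be binary")
  labels <- sort(species_tree$tip.label)
  extra <- setdiff(unique(unlist(lapply(gene_trees, function(t) t$tip.label))),
                   labels)
  if (length(extra)) {
    warn(paste0("gene-tree species absent from species tree are ignored: ",
                paste(head(extra, 5), collapse = ", ")))
    gene_trees <- lapply(gene_trees, function(t) {
      keep <- intersect(t$tip.label, labels)
      if (length(keep) < 2) return(NULL)
      restrict_tree(t, keep)
    })
    gene_trees <- Filter(Negate(is.null), gene_trees)
  }
  prep <- prepare_gene_splits(gene_trees, labels)
  fast <- prep$fast
  # per-quintet preprocessing: distribution + 7 rooting costs
  uniq <- unique(vapply(plan$quintet, paste, character(1), collapse = "|"))
  qinfo <- list()
  n_scans <- 0L; n_cost_evals <- 0L
  for (key in uniq) {
    q <- strsplit(key, "|", fixed = TRUE)[[1]]
    catq <- quintet_catalog(q)
    counts <- quintet_counts(prep, q, catq)
    n_scans <- n_scans + length(prep$trees)
    qd <- quintet_distribution(counts, q)
    if (qd$m == 0) { qinfo[[key]] <- list(m = 0L); next }
    tq <- restrict_tree(species_tree, q)
    idx <- quintet_topology_index(tq, catq)
    rts <- quintet_rootings(catq, idx)
    costs <- numeric(nrow(rts))
    for (r in seq_len(nrow(rts))) {
      st <- permute_structure(
        shape_structure(rts$shape[r]),
        topology_index_permutation(rts$sigma[[r]], catq))
      costs[r] <- rooting_cost(st, qd)
      n_cost_evals <- n_cost_evals + 1L
    }
    qinfo[[key]] <- list(m = qd$m, cost = setNames(costs, rts$clade_key),
                         qpos = match(q, labels))
  }
  keys <- vapply(plan$quintet, paste, character(1), collapse = "|")
  informative <- vapply(qinfo[keys], function(x) x$m > 0, logical(1))
  if (!any(informative)) {
    abort("no informative quintets: every sampled quintet had zero support")
  }
  # score every candidate root edge
  er <- enumerate_rootings(species_tree)
  scores <- numeric(nrow(er))
  for (e in seq_len(nrow(er))) {
    cl <- tree_clades(er$tree[[e]])
    if (fast) {
      pos <- lapply(cl, function(s) match(s, labels))
      cmask <- vapply(pos, mask32_of, integer(1))
    }
    sc <- 0
    for (key in keys[informative]) {
      qi <- qinfo[[key]]
      if (fast) {
        qbits <- bitwShiftL(1L, qi$qpos - 1L)
        qmask <- sum(qbits)
        masked <- bitwAnd(cmask, qmask)
        pc <- popcount(masked)
        masked <- unique(masked[pc >= 2 & pc <= 4])
        loc <- vapply(masked, function(p) {
          mask_of(which(bitwAnd(p, qbits) > 0L))
        }, integer(1))
      } else {
        q <- strsplit(key, "|", fixed = TRUE)[[1]]
        inter <- lapply(cl, intersect, q)
        sz <- vapply(inter, length, integer(1))
        inter <- unique(lapply(inter[sz >= 2 & sz <= 4], sort))
        loc <- vapply(inter, function(s) mask_of(match(s, q)), integer(1))
      }
      ck <- paste(sort(loc), collapse = "|")
      cost <- qi$cost[[ck]]
      if (is.null(cost)) abort("internal error: unmatched rooted quintet")
      sc <- sc + cost
    }
    scores[e] <- sc
  }
  ord <- order(scores, er$edge_id)
  rank <- integer(nrow(er)); rank[ord] <- seq_len(nrow(er))
  tied <- abs(scores - min(scores)) <= 1e-12 * max(1, abs(min(scores)))
  best <- ord[1]
  tab <- tibble::tibble(
    edge_id = er$edge_id, score = scores, rank = rank,
    n_informative_quintets = sum(informative), tied = tied)
  tab <- tab[order(tab$rank), ]
  structure(list(
    table = tab,
    root_edge = er$edge_id[best],
    rooted_tree = er$tree[[best]],
    species_tree = species_tree,
    plan = plan,
    quintet_support = tibble::tibble(
      quintet = keys, m = vapply(qinfo[keys], `[[`, integer(1), "m")),
    counters = list(cost_evaluations = n_cost_evals,
                    tree_quintet_scans = n_scans),
    n_tied = sum(tied)
  ), class = "rooting_score_table")
}

#' @export
print.rooting_score_table <- function(x, ...) {
  n <- n_tips(x$species_tree)
  cat("Rooting score table:", nrow(x$table), "candidate root edges on",
      n, "species\n")
  cat("  selected root edge:", x$root_edge,
      if (x$n_tied > 1) sprintf("(tied with %d other edges)", x$n_tied - 1)
      else "", "\n")
  print(head(x$table, 5))
  invisible(x)
}

#' @export
tidy.rooting_score_table <- function(x, ...) x$table

#' @export
glance.rooting_score_table <- function(x, ...) {
  tibble::tibble(
    n_species = n_tips(x$species_tree),
    n_rootings = nrow(x$table),
    root_edge = x$root_edge,
    min_score = min(x$table$score),
    n_tied = x$n_tied,
    n_informative_quintets = x$table$n_informative_quintets[1],
    cost_evaluations = x$counters$cost_evaluations
  )
}

#' @export
autoplot.rooting_score_table <- function(object, ...) {
  d <- object$table
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$rank == 1), size = 2) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40",
                                           `TRUE` = "firebrick"),
                                guide = "none") +
    ggplot2::labs(x = "rank", y = "rooting score",
                  title = "Candidate root edges",
                  subtitle = paste("selected:", object$root_edge)) +
    ggplot2::theme_minimal()
}

#' Root a species tree from multi-copy gene family trees
#'
#' The full pipeline: gene family trees are decomposed into single-copy
#' trees by duplication/loss parsimony ([disco()]), and the species
#' tree is rooted by scoring all of its `2n - 3` rootings against the
#' quintet topology frequencies of those single-copy trees
#' ([score_rootings()]).
#'
#' @param gene_family_trees List of (multi-copy) gene family `phylo`
#'   trees.
#' @param species_tree Unrooted binary species tree on `n >= 5` species.
#' @param mapping A [species_mapping()] from gene-copy labels to
#'   species.
#' @param min_size Minimum leaves of a retained single-copy tree.
#' @param mode,k,seed Quintet sampling options (see
#'   [sample_quintets()]).
#' @return A `rooting_score_table` (see [score_rootings()]), with the
#'   decomposition summary attached as `$disco`.
#' @export
#' @examples
#' \donttest{
#' sp <- parse_newick("(a,b,(c,(d,e)));")
#' gts <- replicate(50, parse_newick("((((a_1,b_1),c_1),d_1),e_1);"),
#'                  simplify = FALSE)
#' disco_qr(gts, sp)$root_edge
#' }
disco_qr <- function(gene_family_trees, species_tree,
                     mapping = species_mapping(), min_size = 4,
                     mode = c("linear", "exhaustive", "random"),
                     k = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (!length(gene_family_trees)) abort("no gene family trees supplied")
  dres <- disco(gene_family_trees, mapping = mapping, min_size = min_size)
  if (!length(dres$trees)) {
    abort("decomposition produced no usable single-copy trees")
  }
  plan <- sample_quintets(species_tree, mode = mode, k = k, seed = seed)
  out <- score_rootings(species_tree, dres$trees, plan)
  out$disco <- glance(dres)
  out
}
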