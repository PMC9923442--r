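# Duplication/loss parsimony rooting and tagging of multi-copy gene family
# trees, and decomposition into single-copy (ortholog) trees.

# species ids for the tips of a tree under a mapping; returns list with
# species character vector (per tip) and integer ids over sorted unique set
tip_species_ids <- function(tree, mapping) {
  sp <- map_species(tree$tip.label, mapping)
  uniq <- sort(unique(sp))
  list(species = sp, ids = match(sp, uniq), levels = uniq)
}

#' Tag a rooted gene family tree with duplication/speciation labels
#'
#' Each internal node is tagged `duplication` when the species sets of
#' (any) two of its child subtrees intersect, and `speciation`
#' otherwise. `dup_count` is the number of duplication nodes, and
#' `loss_proxy` sums, over duplication nodes, the number of species
#' present under exactly one child -- a species-tree-free surrogate for
#' the implied losses, used only to break ties between rootings.
#'
#' @param tree A rooted `phylo` (gene copies at the leaves).
#' @param mapping A [species_mapping()].
#' @return An object of class `tagged_tree`: the tree plus per-node tags
#'   and parsimony counters.
#' @export
#' @examples
#' t <- parse_newick("((A_1,B_1),(A_2,B_2));")
#' tag_gene_tree(t)$dup_count
tag_gene_tree <- function(tree, mapping = species_mapping()) {
  if (!ape::is.rooted(tree)) abort("tree must be rooted")
  m <- tip_species_ids(tree, mapping)
  nt <- n_tips(tree)
  ns <- length(m$levels)
  M <- nt + tree$Nnode
  below <- matrix(FALSE, nrow = ns, ncol = M)
  below[cbind(m$ids, seq_len(nt))] <- TRUE
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  ord <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])
  tags <- rep(NA_character_, M)
  loss <- 0L
  for (v in ord) {
    ch <- kids[[as.character(v)]]
    cs <- below[, ch, drop = FALSE]
    counts <- rowSums(cs)
    isdup <- any(counts >= 2)
    tags[v] <- if (isdup) "duplication" else "speciation"
    if (isdup) loss <- loss + sum(counts == 1L)
    below[, v] <- counts > 0L
  }
  structure(list(
    tree = tree,
    species = m$species,
    tags = tags,
    dup_count = sum(tags == "duplication", na.rm = TRUE),
    loss_proxy = loss,
    mapping = mapping
  ), class = "tagged_tree")
}

#' @export
print.tagged_tree <- function(x, ...) {
  cat("Tagged gene family tree:", n_tips(x$tree), "leaves,",
      length(unique(x$species)), "species\n")
  cat("  duplications:", x$dup_count, "  loss proxy:", x$loss_proxy, "\n")
  if (!is.null(x$root_edge)) cat("  rooted on edge:", x$root_edge, "\n")
  invisible(x)
}

#' @export
tidy.tagged_tree <- function(x, ...) {
  nt <- n_tips(x$tree)
  idx <- which(!is.na(x$tags))
  tibble::tibble(node = idx, tag = x$tags[idx])
}

#' Root a gene family tree by duplication/loss parsimony
#'
#' Scans all `2n' - 3` rootings of an unrooted multi-copy gene tree and
#' returns the tagging of the rooting that minimizes the pair
#' `(dup_count, loss_proxy)` lexicographically; exact ties are broken by
#' the smallest canonical edge identifier. The scan reuses directional
#' species sets so each candidate edge is evaluated incrementally rather
#' than by re-tagging from scratch; [tag_gene_tree()] applied to every
#' rooting from [enumerate_rootings()] is the quadratic reference it
#' must agree with.
#'
#' @inheritParams tag_gene_tree
#' @param tree An unrooted binary `phylo` with at least 3 leaves (a
#'   rooted input is unrooted first; 2-leaf trees are tagged as given).
#' @return A `tagged_tree` with a `root_edge` field (canonical edge id).
#' @export
optimal_root <- function(tree, mapping = species_mapping()) {
  if (n_tips(tree) < 2) abort("need at least 2 leaves")
  if (n_tips(tree) == 2) {
    out <- tag_gene_tree(if (ape::is.rooted(tree)) tree else tree, mapping)
    out$root_edge <- edge_id(tree$tip.label[1], tree$tip.label)
    return(out)
  }
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  if (!ape::is.binary(tree)) abort("tree must be binary")
  m <- tip_species_ids(tree, mapping)
  nt <- n_tips(tree)
  ns <- length(m$levels)
  M <- nt + tree$Nnode
  root <- nt + 1L
  parent <- integer(M); parent[root] <- NA_integer_
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  kids <- vector("list", M)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[k, 2])
  }
  # species sets below / above every node in the stored orientation
  below <- matrix(FALSE, ns, M)
  below[cbind(m$ids, seq_len(nt))] <- TRUE
  post <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])
  for (v in post) below[, v] <- rowSums(below[, kids[[v]], drop = FALSE]) > 0
  above <- matrix(FALSE, ns, M)  # species NOT below v (toward parent)
  pre <- rev(post)
  for (v in pre) {
    for (ch in kids[[v]]) {
      sibs <- setdiff(kids[[v]], ch)
      s <- rowSums(below[, sibs, drop = FALSE]) > 0
      if (!is.na(parent[v])) s <- s | above[, v]
      above[, ch] <- s
    }
  }
  # per internal node and toward-root direction: duplication flag and loss
  dirset <- function(v, d) {
    if (!is.na(parent[v]) && d == parent[v]) above[, v] else below[, d]
  }
  internals <- (nt + 1L):M
  flags <- vector("list", M); losses <- vector("list", M)
  for (v in internals) {
    nb <- c(kids[[v]], if (!is.na(parent[v])) parent[v])
    fv <- numeric(length(nb)); lv <- numeric(length(nb))
    for (i in seq_along(nb)) {
      others <- nb[-i]
      s1 <- dirset(v, others[1]); s2 <- dirset(v, others[2])
      dup <- any(s1 & s2)
      fv[i] <- as.numeric(dup)
      lv[i] <- if (dup) sum(xor(s1, s2)) else 0
    }
    names(fv) <- names(lv) <- as.character(nb)
    flags[[v]] <- fv; losses[[v]] <- lv
  }
  # root-node contribution for rooting on the edge above v
  rootdup <- numeric(nrow(tree$edge)); rootloss <- numeric(nrow(tree$edge))
  for (k in seq_len(nrow(tree$edge))) {
    v <- tree$edge[k, 2]
    dup <- any(below[, v] & above[, v])
    rootdup[k] <- as.numeric(dup)
    rootloss[k] <- if (dup) sum(xor(below[, v], above[, v])) else 0
  }
  # base edge: first edge out of the basal node
  toward <- function(v, d) flags[[v]][[as.character(d)]]
  toward_l <- function(v, d) losses[[v]][[as.character(d)]]
  base_k <- which(tree$edge[, 1] == root)[1]
  c0 <- tree$edge[base_k, 2]
  dup0 <- toward(root, c0) + sum(vapply(
    setdiff(internals, root), function(v) toward(v, parent[v]), numeric(1)))
  loss0 <- toward_l(root, c0) + sum(vapply(
    setdiff(internals, root), function(v) toward_l(v, parent[v]), numeric(1)))
  nE <- nrow(tree$edge)
  dup_tot <- rep(NA_real_, nE); loss_tot <- rep(NA_real_, nE)
  edge_row <- matrix(NA_integer_, M, M)
  for (k in seq_len(nE)) edge_row[tree$edge[k, 1], tree$edge[k, 2]] <- k
  # DFS over edges from the base edge, updating only the pivot node
  walk <- function(k, dup, loss) {
    repeat {
      dup_tot[k] <<- dup; loss_tot[k] <<- loss
      v <- tree$edge[k, 2]
      if (v <= nt) return(invisible())
      ws <- kids[[v]]
      for (w in ws[-1]) {
        walk(edge_row[v, w],
             dup - toward(v, parent[v]) + toward(v, w),
             loss - toward_l(v, parent[v]) + toward_l(v, w))
      }
      w <- ws[1]
      dup <- dup - toward(v, parent[v]) + toward(v, w)
      loss <- loss - toward_l(v, parent[v]) + toward_l(v, w)
      k <- edge_row[v, w]
    }
  }
  # seed every edge incident to the basal node, then descend
  for (c0i in kids[[root]]) {
    k0 <- edge_row[root, c0i]
    d0 <- dup0 - toward(root, c0) + toward(root, c0i)
    l0 <- loss0 - toward_l(root, c0) + toward_l(root, c0i)
    walk(k0, d0, l0)
  }
  dup_tot <- dup_tot + rootdup
  loss_tot <- loss_tot + rootloss
  sets <- edge_tip_sets(tree)
  ids <- vapply(sets, edge_id, character(1), all_labels = tree$tip.label)
  ordk <- order(dup_tot, loss_tot, ids)
  best <- ordk[1]
  out <- tag_gene_tree(root_tree_at(tree, best), mapping)
  out$root_edge <- ids[best]
  out$scan <- tibble::tibble(edge_id = ids, dup_count = as.integer(dup_tot),
                             loss_proxy = as.integer(loss_tot))
  out
}

#' Decompose a tagged gene family tree into single-copy trees
#'
#' Duplication nodes are processed bottom-up; at each one the child
#' subtree covering fewer distinct species (ties: fewer leaves, then the
#' child not containing the lexicographically smallest leaf label) is
#' detached and emitted, keeping the larger subtree in place. The final
#' retained tree is emitted last. Pieces with fewer than `min_size`
#' leaves are dropped and their leaf count recorded, so that emitted
#' leaves plus discarded leaves account for every input leaf.
#'
#' @param tagged A `tagged_tree` from [tag_gene_tree()] or
#'   [optimal_root()].
#' @param min_size Minimum number of leaves of an emitted tree
#'   (default 4, small enough to be useless for quintet estimation
#'   otherwise).
#' @return An object of class `disco_decomposition` with elements
#'   `trees` (list of rooted single-copy `phylo`, gene-copy labels),
#'   `provenance` (tibble), and `n_discarded_leaves`.
#' @export
decompose_tagged <- function(tagged, min_size = 4) {
  stopifnot(inherits(tagged, "tagged_tree"), min_size >= 2)
  tree <- tagged$tree
  nt <- n_tips(tree)
  sp <- tagged$species
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  post <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])
  retained <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) retained[[i]] <- i
  emitted <- list(); emitted_at <- integer()
  for (v in post) {
    ch <- kids[[as.character(v)]]
    sets <- retained[ch]
    if (identical(tagged$tags[v], "duplication")) {
      detach_one <- function(sets) {
        nsp <- vapply(sets, function(s) length(unique(sp[s])), integer(1))
        nl <- vapply(sets, length, integer(1))
        minlab <- vapply(sets, function(s) min(tree$tip.label[s]), character(1))
        # detach fewest species; ties: fewest leaves, then keep the side
        # holding the lexicographically smallest leaf label
        d <- order(nsp, nl, -xtfrm(minlab))[1]
        emitted[[length(emitted) + 1L]] <<- sets[[d]]
        emitted_at[length(emitted_at) + 1L] <<- v
        sets[-d]
      }
      pairwise_overlap <- function(sets) {
        spsets <- lapply(sets, function(s) unique(sp[s]))
        tab <- table(unlist(spsets))
        any(tab >= 2)
      }
      if (length(sets) == 2) {
        # binary duplication nodes always shed one child
        sets <- detach_one(sets)
      } else {
        # multifurcations shed until remaining children are disjoint
        while (length(sets) >= 2 && pairwise_overlap(sets)) {
          sets <- detach_one(sets)
        }
      }
    }
    retained[[v]] <- sort(unlist(sets))
  }
  emitted <- c(emitted, retained[nt + 1L])
  emitted_at <- c(emitted_at, NA_integer_)
  sizes <- vapply(emitted, length, integer(1))
  kept <- sizes >= min_size
  trees <- lapply(which(kept), function(i) {
    restrict_tree(tree, tree$tip.label[emitted[[i]]])
  })
  # single-copy guarantee, asserted on every run
  for (i in seq_along(trees)) {
    spi <- sp[match(trees[[i]]$tip.label, tree$tip.label)]
    if (anyDuplicated(spi)) {
      abort("internal error: decomposition produced a multi-copy tree")
    }
  }
  structure(list(
    trees = trees,
    provenance = tibble::tibble(
      piece = seq_along(emitted),
      detached_at = emitted_at,
      n_leaves = sizes,
      n_species = vapply(emitted, function(s) length(unique(sp[s])), integer(1)),
      kept = kept
    ),
    n_discarded_leaves = sum(sizes[!kept]),
    min_size = min_size
  ), class = "disco_decomposition")
}

#' @export
print.disco_decomposition <- function(x, ...) {
  cat("Decomposition:", length(x$trees), "single-copy trees kept,",
      x$n_discarded_leaves, "leaves discarded (min_size =", x$min_size, ")\n")
  invisible(x)
}

#' @export
tidy.disco_decomposition <- function(x, ...) x$provenance

#' Decompose gene family trees into single-copy gene trees
#'
#' The full decomposition stage: each unrooted multi-copy gene family
#' tree is rooted and tagged by duplication/loss parsimony
#' ([optimal_root()]) and split at its duplication nodes
#' ([decompose_tagged()]). Output leaves are relabeled with species
#' names, ready for quintet-based rooting. Trees that fail to parse or
#' map are skipped and counted.
#'
#' @param gene_family_trees List of `phylo` objects (rooted or
#'   unrooted; single-copy trees pass through up to rooting).
#' @param mapping A [species_mapping()].
#' @param min_size Minimum leaves per output tree (default 4).
#' @return An object of class `disco_result` with elements `trees`
#'   (list of single-copy `phylo`, species-labeled), `provenance`
#'   (tibble: gene, piece, n_leaves, kept), and counts
#'   (`n_input_leaves`, `n_output_leaves`, `n_discarded_leaves`,
#'   `n_errors`).
#' @export
disco <- function(gene_family_trees, mapping = species_mapping(), min_size = 4) {
  stopifnot(is.list(gene_family_trees))
  trees <- list(); prov <- list()
  n_in <- 0L; n_disc <- 0L; n_err <- 0L
  for (g in seq_along(gene_family_trees)) {
    gt <- gene_family_trees[[g]]
    n_in <- n_in + n_tips(gt)
    res <- tryCatch({
      if (n_tips(gt) < 3) {
        sp <- map_species(gt$tip.label, mapping)
        if (anyDuplicated(sp) || n_tips(gt) < min_size) {
          list(trees = list(), provenance = NULL,
               n_discarded_leaves = n_tips(gt))
        } else {
          list(trees = list(gt),
               provenance = tibble::tibble(piece = 1L, detached_at = NA_integer_,
                                           n_leaves = n_tips(gt),
                                           n_species = n_tips(gt), kept = TRUE),
               n_discarded_leaves = 0L)
        }
      } else {
        dec <- decompose_tagged(optimal_root(gt, mapping), min_size)
        unclass(dec)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_err <- n_err + 1L
      warn(sprintf("gene tree %d skipped: %s", g, conditionMessage(res)))
      next
    }
    n_disc <- n_disc + res$n_discarded_leaves
    for (tr in res$trees) {
      tr$tip.label <- map_species(tr$tip.label, mapping)
      trees[[length(trees) + 1L]] <- tr
    }
    if (!is.null(res$provenance)) {
      pv <- res$provenance
      pv$gene <- g
      prov[[length(prov) + 1L]] <- pv
    }
  }
  structure(list(
    trees = trees,
    provenance = if (length(prov)) dplyr::bind_rows(prov) else tibble::tibble(),
    n_input_leaves = n_in,
    n_output_leaves = sum(vapply(trees, n_tips, integer(1))),
    n_discarded_leaves = n_disc,
    n_errors = n_err
  ), class = "disco_result")
}

#' @export
print.disco_result <- function(x, ...) {
  cat("DISCO decomposition:", length(x$trees), "single-copy trees from",
      length(unique(x$provenance$gene)), "gene families\n")
  cat("  leaves: ", x$n_input_leaves, " in, ", x$n_output_leaves, " out, ",
      x$n_discarded_leaves, " discarded; errors: ", x$n_errors, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.disco_result <- function(x, ...) x$provenance

#' @export
glance.disco_result <- function(x, ...) {
  tibble::tibble(
    n_genes = length(unique(x$provenance$gene)),
    n_trees = length(x$trees),
    n_input_leaves = x$n_input_leaves,
    n_output_leaves = x$n_output_leaves,
    n_discarded_leaves = x$n_discarded_leaves,
    n_errors = x$n_errors
  )
}
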