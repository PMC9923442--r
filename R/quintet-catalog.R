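# Canonical enumeration of 5-taxon tree topologies. An unrooted binary
# tree on five labels is determined by its two disjoint cherry pairs
# (the fifth leaf sits on the path between them), giving 15 topologies;
# each has 7 rootings (5 pendant edges + 2 internal edges), 105 rooted
# topologies in all. Internally a set of taxa is a 5-bit mask over the
# positions of the sorted labels.

mask_of <- function(positions) sum(bitwShiftL(1L, positions - 1L))
mask_bits <- function(m) which(bitwAnd(m, bitwShiftL(1L, 0:4)) > 0L)

popcount16 <- function() {
  pc <- .multiroot_cache$pc16
  if (is.null(pc)) {
    pc <- as.integer(colSums(matrix(as.integer(intToBits(0:65535)), nrow = 32)))
    .multiroot_cache$pc16 <- pc
  }
  pc
}

popcount <- function(x) {
  pc <- popcount16()
  pc[bitwAnd(x, 65535L) + 1L] + pc[bitwShiftR(x, 16L) + 1L]
}

#' Catalog of the 15 unrooted quintet topologies on five labels
#'
#' Topologies are indexed 1..15 in lexicographic order of a canonical
#' Newick form `((a,b),(c,d),e);` (cherries sorted internally and by
#' first member). Each topology has exactly 7 rootings, classified into
#' the three rooted 5-leaf shapes.
#'
#' @param labels Five distinct strings (sorted internally).
#' @return An object of class `quintet_catalog` with fields `labels`,
#'   `topologies` (tibble: `index`, `cherry1`, `cherry2` as bit masks,
#'   `newick`), and `pair_index` (32 x 32 lookup from cherry-mask pairs
#'   to index).
#' @export
quintet_catalog <- function(labels) {
  if (length(labels) != 5 || anyDuplicated(labels)) {
    abort("need exactly 5 distinct labels")
  }
  labels <- sort(labels)
  key <- paste(labels, collapse = "\r")
  hit <- .multiroot_cache$catalogs[[key]]
  if (!is.null(hit)) return(hit)
  pairs <- utils::combn(5L, 2L)
  rows <- list()
  for (i in seq_len(ncol(pairs))) for (j in seq_len(ncol(pairs))) {
    a <- pairs[, i]; b <- pairs[, j]
    if (i < j && !length(intersect(a, b))) {
      m1 <- mask_of(a); m2 <- mask_of(b)
      if (m1 > m2) { tmp <- m1; m1 <- m2; m2 <- tmp }
      c1 <- mask_bits(m1); c2 <- mask_bits(m2)
      if (labels[c1[1]] > labels[c2[1]]) { tmp <- c1; c1 <- c2; c2 <- tmp }
      mid <- setdiff(1:5, c(c1, c2))
      nwk <- sprintf("((%s,%s),(%s,%s),%s);",
                     labels[c1[1]], labels[c1[2]],
                     labels[c2[1]], labels[c2[2]], labels[mid])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cherry1 = m1, cherry2 = m2, mid = mask_of(mid), newick = nwk)
    }
  }
  tab <- dplyr::bind_rows(rows)
  tab <- tab[order(tab$newick), ]
  tab$index <- seq_len(nrow(tab))
  tab <- tab[, c("index", "cherry1", "cherry2", "mid", "newick")]
  pair_index <- matrix(-1L, 32, 32)
  for (r in seq_len(nrow(tab))) {
    pair_index[tab$cherry1[r] + 1L, tab$cherry2[r] + 1L] <- tab$index[r] - 1L
  }
  out <- structure(list(labels = labels, topologies = tab,
                        pair_index = pair_index),
                   class = "quintet_catalog")
  if (is.null(.multiroot_cache$catalogs)) .multiroot_cache$catalogs <- list()
  .multiroot_cache$catalogs[[key]] <- out
  out
}

#' @export
print.quintet_catalog <- function(x, ...) {
  cat("Quintet catalog on {", paste(x$labels, collapse = ", "), "}: ",
      nrow(x$topologies), " unrooted topologies x 7 rootings\n", sep = "")
  invisible(x)
}

# catalog index of an unrooted 5-leaf binary phylo (labels must match)
quintet_topology_index <- function(tree, catalog) {
  stopifnot(n_tips(tree) == 5)
  pos <- match(tree$tip.label, catalog$labels)
  if (anyNA(pos)) abort("tree labels do not match catalog")
  sets <- edge_tip_sets(tree)
  masks <- vapply(sets, function(s) mask_of(pos[match(s, tree$tip.label)]),
                  integer(1))
  pairs <- unique(c(masks[popcount(masks) == 2],
                    bitwAnd(31L, bitwNot(masks[popcount(masks) == 3]))))
  pairs <- setdiff(pairs, c(0L))
  if (length(pairs) != 2) abort("tree is not a resolved binary quintet")
  a <- min(pairs); b <- max(pairs)
  idx <- catalog$pair_index[a + 1L, b + 1L]
  if (idx < 0) abort("internal error: unknown cherry pair")
  idx + 1L
}

#' The seven rootings of one catalog topology
#'
#' @param catalog A [quintet_catalog()].
#' @param index Topology index in 1..15.
#' @return A tibble with one row per rooting: `edge_id` (canonical
#'   bipartition), `shape` (`caterpillar`, `balanced`,
#'   `pseudo_caterpillar`), `sigma` (list-column: permutation mapping
#'   shape-representative leaf i to label position `sigma[i]`), and
#'   `clade_key` (the rooted topology's clade masks, sorted and joined,
#'   a unique identifier of the rooted tree).
#' @export
quintet_rootings <- function(catalog, index) {
  row <- catalog$topologies[catalog$topologies$index == index, ]
  if (!nrow(row)) abort("bad topology index")
  P <- mask_bits(row$cherry1); Q <- mask_bits(row$cherry2)
  mid <- mask_bits(row$mid)
  mP <- row$cherry1; mQ <- row$cherry2; mE <- row$mid
  lab <- catalog$labels
  rootings <- list()
  add <- function(edge_labels, shape, sigma, clades) {
    rootings[[length(rootings) + 1L]] <<- tibble::tibble(
      edge_id = edge_id(edge_labels, lab),
      shape = shape,
      sigma = list(sigma),
      clade_key = paste(sort(clades), collapse = "|"))
  }
  # pendant rootings within a cherry: caterpillar
  for (sw in list(P, rev(P))) {
    x <- sw[1]; y <- sw[2]
    add(lab[x], "caterpillar", c(Q, mid, y, x),
        c(mQ, bitwOr(mQ, mE), bitwOr(bitwOr(mQ, mE), mask_of(y))))
  }
  for (sw in list(Q, rev(Q))) {
    x <- sw[1]; y <- sw[2]
    add(lab[x], "caterpillar", c(P, mid, y, x),
        c(mP, bitwOr(mP, mE), bitwOr(bitwOr(mP, mE), mask_of(y))))
  }
  # pendant rooting on the middle leaf: pseudo-caterpillar
  add(lab[mid], "pseudo_caterpillar", c(P, Q, mid), c(mP, mQ, bitwOr(mP, mQ)))
  # internal-edge rootings: balanced
  add(lab[P], "balanced", c(Q, mid, P), c(mQ, bitwOr(mQ, mE), mP))
  add(lab[Q], "balanced", c(P, mid, Q), c(mP, bitwOr(mP, mE), mQ))
  dplyr::bind_rows(rootings)
}

#' Classify the shape of a rooted 5-taxon tree
#'
#' The three unlabeled shapes of rooted binary 5-leaf trees are the
#' caterpillar `((((a,b),c),d),e)`, the balanced tree
#' `(((a,b),c),(d,e))`, and the pseudo-caterpillar
#' `(((a,b),(c,d)),e)`. They are distinguished by the multiset of their
#' proper clade sizes ({2,3,4}, {2,2,3} and {2,2,4} respectively).
#'
#' @param tree A rooted binary `phylo` on 5 leaves.
#' @return One of `"caterpillar"`, `"balanced"`, `"pseudo_caterpillar"`.
#' @export
classify_quintet_shape <- function(tree) {
  if (!ape::is.rooted(tree) || n_tips(tree) != 5 || !ape::is.binary(tree)) {
    abort("need a rooted binary tree on 5 leaves")
  }
  sizes <- sort(vapply(tree_clades(tree), length, integer(1)))
  key <- paste(sizes, collapse = ",")
  switch(key,
         "2,3,4" = "caterpillar",
         "2,2,3" = "balanced",
         "2,2,4" = "pseudo_caterpillar",
         abort("unrecognized clade structure"))
}

# shape and representative-to-actual permutation of a rooted quintet.
# sigma[i] = position (in sorted label order) of the leaf playing role
# q_i of the shape representative; caterpillar rep ((((q1,q2),q3),q4),q5),
# balanced rep (((q1,q2),q3),(q4,q5)), pseudo rep (((q1,q2),(q3,q4)),q5).
quintet_shape_sigma <- function(tree, catalog) {
  pos <- match(tree$tip.label, catalog$labels)
  cl <- tree_clades(tree)
  masks <- vapply(cl, function(s) mask_of(pos[match(s, tree$tip.label)]),
                  integer(1))
  sz <- popcount(masks)
  o <- order(sz)
  masks <- masks[o]; sz <- sz[o]
  full <- 31L
  if (identical(sz, c(2L, 3L, 4L))) {
    shape <- "caterpillar"
    x12 <- mask_bits(masks[1])
    x3 <- mask_bits(bitwAnd(masks[2], bitwNot(masks[1])))
    x4 <- mask_bits(bitwAnd(masks[3], bitwNot(masks[2])))
    x5 <- mask_bits(bitwAnd(full, bitwNot(masks[3])))
    sigma <- c(x12, x3, x4, x5)
  } else if (identical(sz, c(2L, 2L, 3L))) {
    shape <- "balanced"
    inner <- if (bitwAnd(masks[1], masks[3]) == masks[1]) masks[1] else masks[2]
    outer <- if (inner == masks[1]) masks[2] else masks[1]
    x3 <- bitwAnd(masks[3], bitwNot(inner))
    sigma <- c(mask_bits(inner), mask_bits(x3), mask_bits(outer))
  } else if (identical(sz, c(2L, 2L, 4L))) {
    shape <- "pseudo_caterpillar"
    x5 <- bitwAnd(full, bitwNot(masks[3]))
    sigma <- c(mask_bits(masks[1]), mask_bits(masks[2]), mask_bits(x5))
  } else {
    abort("unrecognized clade structure")
  }
  list(shape = shape, sigma = sigma)
}

# permutation action on topology indices: sigma maps representative
# position i to actual position sigma[i]; returns pi with pi[t] = index
# of the relabeled topology t.
topology_index_permutation <- function(sigma, catalog) {
  remap <- function(m) mask_of(sigma[mask_bits(m)])
  tab <- catalog$topologies
  vapply(seq_len(nrow(tab)), function(r) {
    a <- remap(tab$cherry1[r]); b <- remap(tab$cherry2[r])
    catalog$pair_index[min(a, b) + 1L, max(a, b) + 1L] + 1L
  }, integer(1))
}
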