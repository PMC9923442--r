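#' Parse a Newick string into a phylo tree
#'
#' Thin validating wrapper around [ape::read.tree()]. A top-level
#' bifurcation yields a rooted tree and a top-level multifurcation an
#' unrooted one, unless `rooted` overrides the reading. Leaf labels must
#' be unique; polytomies are allowed.
#'
#' @param text A Newick string (terminating `;` optional).
#' @param rooted Optional logical. `TRUE` forces a rooted interpretation
#'   (an error if the top-level split is not binary), `FALSE` unroots the
#'   parsed tree.
#' @return An object of class `phylo`.
#' @export
#' @examples
#' parse_newick("((a,b),(c,d));")
#' parse_newick("(a,b,(c,d));")
parse_newick <- function(text, rooted = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL,
    warning = function(w) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    # locate first structurally suspicious character for the message
    bad <- regexpr("[^(),:;[:alnum:]_.' \\t-]", text)
    pos <- if (bad > 0) bad else nchar(text)
    abort(sprintf("malformed Newick near character %d: %s", pos,
                  substr(text, max(1, pos - 10), min(nchar(text), pos + 10))),
          class = "multiroot_parse_error")
  }
  validate_tree(tr)
  if (isTRUE(rooted) && !ape::is.rooted(tr)) {
    abort("tree has a top-level multifurcation; cannot interpret as rooted",
          class = "multiroot_parse_error")
  }
  if (isFALSE(rooted) && ape::is.rooted(tr)) tr <- ape::unroot(tr)
  tr
}

validate_tree <- function(tr) {
  if (anyDuplicated(tr$tip.label)) {
    dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
    abort(paste0("duplicate leaf labels: ", paste(dup, collapse = ", ")),
          class = "multiroot_validation_error")
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    abort("negative branch lengths", class = "multiroot_validation_error")
  }
  invisible(tr)
}

#' Write a tree to Newick
#'
#' @param tree A `phylo` object.
#' @return A single Newick string (with trailing `;`).
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Read/write multi-tree Newick files (one tree per line)
#'
#' @param path File path.
#' @return `read_tree_file()`: a list of `phylo` objects.
#' @export
read_tree_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lapply(lines, parse_newick)
}

#' @param trees A list of `phylo` objects.
#' @rdname read_tree_file
#' @export
write_tree_file <- function(trees, path) {
  writeLines(vapply(trees, ape::write.tree, character(1)), path)
}

is_binary_unrooted <- function(tr) {
  !ape::is.rooted(tr) && ape::is.binary(tr)
}

n_tips <- function(tr) length(tr$tip.label)

# --- canonical edge / clade identifiers ------------------------------------

canonical_side <- function(labels, all_labels) {
  other <- setdiff(all_labels, labels)
  a <- sort(labels); b <- sort(other)
  if (length(a) < length(b)) return(a)
  if (length(b) < length(a)) return(b)
  if (paste(a, collapse = "|") <= paste(b, collapse = "|")) a else b
}

#' Canonical identifier of a bipartition (edge) of a tree
#'
#' An edge of an unrooted tree is identified by the leaf-label
#' bipartition it induces, written as the smaller side (ties broken
#' lexicographically), sorted and joined by `|`. These identifiers are
#' stable across traversal orders and rerootings, so rooting score
#' tables are joinable across runs.
#'
#' @param labels Character vector: the leaf labels on one side of the edge.
#' @param all_labels All leaf labels of the tree.
#' @return A single string.
#' @export
edge_id <- function(labels, all_labels) {
  paste(canonical_side(labels, all_labels), collapse = "|")
}

# tips below each edge of a phylo (list indexed by edge row)
edge_tip_sets <- function(tr) {
  nt <- n_tips(tr)
  nn <- tr$Nnode
  below <- vector("list", nt + nn)
  for (i in seq_len(nt)) below[[i]] <- tr$tip.label[i]
  ord <- ape::reorder.phylo(tr, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1]; ch <- ord$edge[k, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  lapply(seq_len(nrow(tr$edge)), function(k) below[[tr$edge[k, 2]]])
}

#' Enumerate all rootings of an unrooted binary tree
#'
#' An unrooted binary tree on `n` leaves has `2n - 3` edges and hence
#' `2n - 3` candidate rootings, obtained by subdividing each edge with a
#' new root node.
#'
#' @param tree An unrooted binary `phylo` with `n >= 3` leaves.
#' @return A tibble with columns `edge_id` (canonical bipartition string)
#'   and `tree` (list-column of rooted `phylo` objects), ordered by
#'   `edge_id`.
#' @export
enumerate_rootings <- function(tree) {
  if (ape::is.rooted(tree)) abort("tree must be unrooted")
  if (!ape::is.binary(tree)) abort("tree must be binary")
  if (n_tips(tree) < 3) abort("need at least 3 leaves")
  all_l <- tree$tip.label
  sets <- edge_tip_sets(tree)
  ids <- vapply(sets, edge_id, character(1), all_labels = all_l)
  rooted <- lapply(seq_along(ids), function(k) root_tree_at(tree, k))
  out <- tibble::tibble(edge_id = ids, tree = rooted)
  out[order(out$edge_id), ]
}

# root an unrooted phylo on edge row k (midpoint of the edge)
root_tree_at <- function(tree, k) {
  had_len <- !is.null(tree$edge.length)
  tr <- tree
  if (!had_len) tr$edge.length <- rep(1, nrow(tr$edge))
  node <- tr$edge[k, 2]
  len <- tr$edge.length[k]
  pos <- if (len > 0) len / 2 else 0
  out <- phytools::reroot(tr, node.number = node, position = pos)
  if (!had_len) out$edge.length <- NULL
  out$node.label <- NULL
  out
}

#' Root an unrooted tree on a named edge
#'
#' @param tree Unrooted binary `phylo`.
#' @param id Canonical edge identifier (see [edge_id()]).
#' @return A rooted `phylo` with the root subdividing that edge.
#' @export
root_at_edge <- function(tree, id) {
  sets <- edge_tip_sets(tree)
  ids <- vapply(sets, edge_id, character(1), all_labels = tree$tip.label)
  k <- match(id, ids)
  if (is.na(k)) abort(paste0("no edge with id ", id))
  root_tree_at(tree, k)
}

#' Restrict a tree to a subset of its leaves
#'
#' Returns the induced subtree on `taxa` with all degree-2 nodes
#' suppressed. For a rooted input the result is rooted at the MRCA of
#' `taxa`.
#'
#' @param tree A `phylo`.
#' @param taxa Character vector of leaf labels, a subset of
#'   `tree$tip.label`, of size at least 2.
#' @return A `phylo`.
#' @export
restrict_tree <- function(tree, taxa) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing)) {
    abort(paste0("taxa not in tree: ", paste(missing, collapse = ", ")))
  }
  if (length(taxa) < 2) abort("need at least 2 taxa")
  if (length(taxa) == n_tips(tree)) return(tree)
  ape::keep.tip(tree, taxa)
}

#' Proper nontrivial clades of a rooted tree
#'
#' A clade is the leaf set below an internal node. Singleton clades and
#' the full leaf set are excluded, so a rooted binary tree on `n` leaves
#' has exactly `n - 2` clades, and the symmetric difference of the clade
#' sets of two rootings of the same topology is at most `2n - 4`.
#'
#' @param tree A rooted `phylo`.
#' @return A list of sorted character vectors (one per clade), named by
#'   the `|`-joined clade key.
#' @export
tree_clades <- function(tree) {
  if (!ape::is.rooted(tree)) abort("tree must be rooted")
  nt <- n_tips(tree)
  below <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) below[[i]] <- tree$tip.label[i]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1]; ch <- ord$edge[k, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  root <- nt + 1L
  internal <- setdiff(seq_len(nt + tree$Nnode), c(seq_len(nt), root))
  cl <- lapply(below[internal], sort)
  cl <- cl[vapply(cl, length, integer(1)) >= 2 &
             vapply(cl, length, integer(1)) < nt]
  cl <- unique(cl)
  names(cl) <- vapply(cl, paste, character(1), collapse = "|")
  cl
}

# nontrivial splits of a tree as canonical keys (unrooted semantics)
tree_split_keys <- function(tree) {
  nt <- n_tips(tree)
  sets <- edge_tip_sets(tree)
  sizes <- vapply(sets, length, integer(1))
  keep <- sizes >= 2 & sizes <= nt - 2
  unique(vapply(sets[keep], edge_id, character(1), all_labels = tree$tip.label))
}
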