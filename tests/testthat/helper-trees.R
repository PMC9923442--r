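# tree generators used across the suite; all draws go through the
# session RNG so tests seed explicitly

random_unrooted_tree <- function(n, labels = NULL) {
  tr <- ape::unroot(ape::rtree(n, tip.label = labels))
  tr$edge.length <- NULL
  tr
}

random_rooted_tree <- function(n, labels = NULL) {
  tr <- ape::rtree(n, tip.label = labels)
  tr$edge.length <- NULL
  tr
}

# random multi-copy gene tree: n_leaves gene copies over n_species
# species, labels SPECIES_copy
random_mul_tree <- function(n_leaves, n_species) {
  sp <- sample(LETTERS[seq_len(n_species)], n_leaves, replace = TRUE)
  labs <- paste0(sp, "_", seq_len(n_leaves))
  random_unrooted_tree(n_leaves, labels = labs)
}

same_unrooted_topology <- function(a, b) {
  setequal(a$tip.label, b$tip.label) &&
    (n_tips(a) < 4 || rf_distance(a, b) == 0)
}

# quadratic reference for optimal_root: tag every rooting
brute_force_root <- function(tree, mapping = species_mapping()) {
  er <- enumerate_rootings(tree)
  tg <- lapply(er$tree, tag_gene_tree, mapping = mapping)
  d <- vapply(tg, `[[`, numeric(1), "dup_count")
  l <- vapply(tg, `[[`, numeric(1), "loss_proxy")
  k <- order(d, l, er$edge_id)[1]
  list(edge = er$edge_id[k], dup = d[k], loss = l[k])
}
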