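test_that("the catalog has 15 topologies x 7 rootings = 105 rooted trees", {
  cat5 <- quintet_catalog(letters[1:5])
  expect_equal(nrow(cat5$topologies), 15)
  expect_error(quintet_catalog(letters[1:4]), "5 distinct")
  all_rootings <- lapply(1:15, quintet_rootings, catalog = cat5)
  expect_true(all(vapply(all_rootings, nrow, integer(1)) == 7))
  # rooted topologies are pairwise distinct: clade keys unique within and
  # across topologies
  keys <- unlist(lapply(seq_along(all_rootings), function(i) {
    paste(i, all_rootings[[i]]$clade_key)
  }))
  expect_length(unique(keys), 105)
  # index <-> topology maps are mutually inverse
  for (i in 1:15) {
    tr <- parse_newick(cat5$topologies$newick[i])
    expect_equal(quintet_topology_index(tr, cat5), i)
  }
})

test_that("rooted shapes classify into caterpillar/balanced/pseudo 60/30/15", {
  expect_equal(classify_quintet_shape(parse_newick("((((a,b),c),d),e);")),
               "caterpillar")
  expect_equal(classify_quintet_shape(parse_newick("(((a,b),c),(d,e));")),
               "balanced")
  expect_equal(classify_quintet_shape(parse_newick("(((a,b),(c,d)),e);")),
               "pseudo_caterpillar")
  expect_error(classify_quintet_shape(parse_newick("(((a,b),c),d);")),
               "5 leaves")
  cat5 <- quintet_catalog(letters[1:5])
  shapes <- unlist(lapply(1:15, function(i) quintet_rootings(cat5, i)$shape))
  expect_equal(sort(as.vector(table(shapes))), c(15, 30, 60))
  expect_equal(sum(shapes == "caterpillar"), 60)
  expect_equal(sum(shapes == "balanced"), 30)
  expect_equal(sum(shapes == "pseudo_caterpillar"), 15)
})

test_that("the coalescent oracle is deterministic and label-equivariant", {
  tr <- parse_newick("((((a:1,b:1):0.4,c:1):0.3,d:1):0.6,e:1);")
  p1 <- msc_quintet_probs(tr, n_samples = 2e4, seed = 9)
  p2 <- msc_quintet_probs(tr, n_samples = 2e4, seed = 9)
  expect_identical(p1, p2)
  expect_equal(sum(p1), 1)
  # relabeling the species permutes the probabilities accordingly
  tr2 <- tr
  tr2$tip.label <- c(a = "d", b = "e", c = "c", d = "a", e = "b")[tr$tip.label]
  p3 <- msc_quintet_probs(tr2, n_samples = 2e5, seed = 10)
  p1b <- msc_quintet_probs(tr, n_samples = 2e5, seed = 11)
  cat5 <- quintet_catalog(letters[1:5])
  perm <- topology_index_permutation(c(4, 5, 3, 1, 2), cat5)
  se3 <- 3 * sqrt(0.25 / 2e5) * 2
  expect_true(all(abs(p3[perm] - p1b) < 3 * sqrt((p1b + 0.01) / 2e5) + se3))
})

test_that("zero internal branches give the uniform topology law", {
  tr <- parse_newick("((((a:1,b:1):0,c:1):0,d:1):0,e:1);")
  p <- msc_quintet_probs(tr, n_samples = 2e5, seed = 3)
  se <- sqrt((1 / 15) * (14 / 15) / 2e5)
  expect_true(all(abs(p - 1 / 15) < 3.5 * se))
})

test_that("long internal branches concentrate on the matching topology", {
  tr <- parse_newick("((((a:1,b:1):20,c:1):20,d:1):20,e:1);")
  p <- msc_quintet_probs(tr, n_samples = 2e4, seed = 4)
  cat5 <- quintet_catalog(letters[1:5])
  idx <- quintet_topology_index(ape::unroot(parse_newick("((((a,b),c),d),e);")),
                                cat5)
  expect_gte(p[idx], 0.999)
})

test_that("the matching topology dominates except in the anomaly zone", {
  st <- shape_structure("caterpillar")
  catq <- quintet_catalog(paste0("q", 1:5))
  rep_tree <- shape_representative("caterpillar")
  match_idx <- quintet_topology_index(ape::unroot(rep_tree), catq)
  beaten <- st$G[st$G[, 1] == match_idx, 2]
  # the caterpillar has anomalous gene trees: with both lower internal
  # branches short and the top branch long, the two-cherries topology
  # ((q1,q2),(q3,q4),q5) overtakes the matching topology (star-tree
  # limits 1/9 vs 1/18), so that one pair is order-flipping and must be
  # omitted; every other topology is strictly dominated
  anomalous <- catq$pair_index[mask_of(c(1, 2)) + 1L,
                               mask_of(c(3, 4)) + 1L] + 1L
  expect_setequal(beaten, setdiff(1:15, c(match_idx, anomalous)))
  om <- paste(st$omitted[, 1], st$omitted[, 2])
  expect_true(paste(min(match_idx, anomalous),
                    max(match_idx, anomalous)) %in% om)
  # and never the reverse order
  expect_false(any(st$G[, 1] == anomalous & st$G[, 2] == match_idx))
  # outside the anomaly zone the matching topology is the maximum
  tr <- rep_tree
  tr$edge.length <- rep(1, nrow(tr$edge))
  p <- msc_quintet_probs(tr, n_samples = 2e5, seed = 12)
  expect_equal(unname(which.max(p)), match_idx)
  # equality relation is symmetric-consistent: no pair both equal and ordered
  ek <- paste(st$E[, 1], st$E[, 2])
  gk <- c(paste(st$G[, 1], st$G[, 2]), paste(st$G[, 2], st$G[, 1]))
  expect_length(intersect(ek, gk), 0)
})

test_that("structures differ between shapes (rooting is identifiable)", {
  sts <- lapply(c("caterpillar", "balanced", "pseudo_caterpillar"),
                shape_structure)
  sig <- vapply(sts, function(s) paste(nrow(s$E), nrow(s$G),
                                       paste(t(s$E), collapse = ","),
                                       paste(t(s$G), collapse = ",")), "")
  expect_length(unique(sig), 3)
})

test_that("order structures are permutation-covariant", {
  # two caterpillars related by a relabeling: the pipeline structure of
  # one must map exactly onto the other's under the induced index action
  t1 <- parse_newick("((((a,b),c),d),e);")
  t2 <- parse_newick("((((d,c),e),a),b);")
  s1 <- quintet_order_structure(t1)
  s2 <- quintet_order_structure(t2)
  cat5 <- quintet_catalog(letters[1:5])
  # relabeling a->d, b->c, c->e, d->a, e->b maps t1 onto t2
  perm <- topology_index_permutation(c(4, 3, 5, 1, 2), cat5)
  key <- function(m) sort(paste(m[, 1], m[, 2]))
  ekey <- function(m) sort(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
  expect_identical(ekey(matrix(perm[s1$E], ncol = 2)), ekey(s2$E))
  expect_identical(key(matrix(perm[s1$G], ncol = 2)), key(s2$G))
})

test_that("an independent re-derivation never contradicts the cached structure", {
  # fresh seed, fresh draws: verdicts may drop to 'omitted' but must not
  # conflict (equality vs strict order, or opposite orders)
  t1 <- parse_newick("((((a,b),c),d),e);")
  cached <- quintet_order_structure(t1)
  fresh <- derive_order_structure(t1, n_draws = 100, n_samples = 1e4,
                                  seed = 4242)
  gk_cached <- paste(cached$G[, 1], cached$G[, 2])
  gk_fresh <- paste(fresh$G[, 1], fresh$G[, 2])
  rev_fresh <- paste(fresh$G[, 2], fresh$G[, 1])
  expect_length(intersect(gk_cached, rev_fresh), 0)
  ek_fresh <- c(paste(fresh$E[, 1], fresh$E[, 2]),
                paste(fresh$E[, 2], fresh$E[, 1]))
  expect_length(intersect(gk_cached, ek_fresh), 0)
})

test_that("structures are branch-length invariant on held-out draws", {
  st <- shape_structure("caterpillar")
  tr <- shape_representative("caterpillar")
  nt <- 5L
  internal <- which(tr$edge[, 2] > nt)
  set.seed(555)
  n <- 2e4
  for (d in 1:10) {
    tr$edge.length <- rep(1, nrow(tr$edge))
    tr$edge.length[internal] <- runif(length(internal), 0.05, 2.0)
    p <- msc_quintet_probs(tr, n_samples = n, seed = NULL)
    if (nrow(st$E)) {
      dif <- abs(p[st$E[, 1]] - p[st$E[, 2]])
      se <- sqrt((p[st$E[, 1]] + p[st$E[, 2]]) / n)
      expect_true(all(dif <= 4.5 * se + 1e-9))
    }
    if (nrow(st$G)) {
      dif <- p[st$G[, 1]] - p[st$G[, 2]]
      se <- sqrt((p[st$G[, 1]] + p[st$G[, 2]]) / n)
      expect_true(all(dif > -4.5 * se))
    }
  }
})

test_that("rooting cost is zero on uniform input and on model frequencies", {
  t1 <- parse_newick("((((a,b),c),d),e);")
  cat5 <- quintet_catalog(letters[1:5])
  st <- quintet_order_structure(t1)
  u <- quintet_distribution(rep(10L, 15), letters[1:5])
  expect_equal(rooting_cost(st, u), 0)
  # model-generated frequencies: cost within Monte-Carlo noise of zero
  tr <- t1
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr$edge.length[tr$edge[, 2] > 5] <- c(0.8, 0.3, 0.5)
  n <- 1e5
  p <- msc_quintet_probs(tr, n_samples = n, seed = 77)
  qd <- quintet_distribution(as.integer(round(p * n)), letters[1:5])
  bound <- 3 * (nrow(st$E) + nrow(st$G)) * sqrt(0.5 / n)
  expect_lt(rooting_cost(st, qd), bound)
  # a point mass on the matching topology: zero for the true rooting,
  # positive for at least one alternative
  match_idx <- quintet_topology_index(ape::unroot(t1), cat5)
  pm <- integer(15); pm[match_idx] <- 100L
  qpm <- quintet_distribution(pm, letters[1:5])
  expect_equal(rooting_cost(st, qpm), 0)
  # a rooted quintet on a different unrooted topology predicts a
  # different maximum, so the point mass violates its orderings
  alt <- quintet_order_structure(parse_newick("((((a,c),b),d),e);"))
  expect_gt(rooting_cost(alt, qpm), 0)
  # zero support must be refused
  z <- quintet_distribution(integer(15), letters[1:5])
  expect_error(rooting_cost(st, z), "zero support")
})
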