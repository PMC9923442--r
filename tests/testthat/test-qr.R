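test_that("quintet sampling plans have the promised sizes", {
  set.seed(3)
  t5 <- random_unrooted_tree(5)
  expect_equal(nrow(sample_quintets(t5, "exhaustive")), 1)
  t7 <- random_unrooted_tree(7)
  expect_equal(nrow(sample_quintets(t7, "exhaustive")), choose(7, 5))
  t21 <- random_unrooted_tree(21)
  expect_equal(nrow(sample_quintets(t21, "exhaustive")), 20349)
  lin <- sample_quintets(t21, "linear")
  expect_equal(nrow(lin), 21 - 3)
  expect_true(all(vapply(lin$quintet, length, integer(1)) == 5))
  expect_true(all(unlist(lin$quintet) %in% t21$tip.label))
  r1 <- sample_quintets(t21, "random", k = 12, seed = 99)
  r2 <- sample_quintets(t21, "random", k = 12, seed = 99)
  expect_identical(r1$quintet, r2$quintet)
  expect_equal(nrow(r1), 12)
  expect_error(sample_quintets(random_unrooted_tree(4), "linear"),
               "at least five")
})

test_that("quintet distributions are counted from resolved restrictions", {
  gt <- parse_newick("((((a,b),c),d),e);")
  qd <- estimate_quintet_distribution(rep(list(gt), 100), letters[1:5])
  expect_equal(qd$m, 100)
  expect_equal(max(qd$freq), 1)
  cat5 <- quintet_catalog(letters[1:5])
  expect_equal(which.max(qd$counts),
               quintet_topology_index(ape::unroot(gt), cat5))
  # gene trees each missing one of the 5 species: zero support, flagged
  gts <- lapply(letters[1:5], function(x) {
    restrict_tree(gt, setdiff(letters[1:5], x))
  })
  qd0 <- estimate_quintet_distribution(gts, letters[1:5])
  expect_equal(qd0$m, 0)
  expect_true(all(is.na(qd0$freq)))
})

test_that("split-based counting equals the direct restriction route", {
  set.seed(47)
  for (rep in 1:15) {
    gts <- replicate(20, {
      labs <- sort(sample(letters[1:9], sample(6:9, 1)))
      random_unrooted_tree(length(labs), labels = labs)
    }, simplify = FALSE)
    q <- sort(sample(letters[1:9], 5))
    cat5 <- quintet_catalog(q)
    qd <- estimate_quintet_distribution(gts, q)
    # independent route: ape restriction + topology identification
    counts <- integer(15); m <- 0L
    for (g in gts) {
      if (!all(q %in% g$tip.label)) next
      r <- restrict_tree(g, q)
      i <- quintet_topology_index(ape::unroot(r), cat5)
      counts[i] <- counts[i] + 1L
      m <- m + 1L
    }
    expect_equal(qd$counts, counts)
    expect_equal(qd$m, m)
  }
})

test_that("on five taxa the score table is the per-quintet cost vector", {
  set.seed(8)
  sp_rooted <- parse_newick("((((a:1,b:1):0.6,c:1):0.6,d:1):0.6,e:1);")
  gts <- replicate(400, simulate_msc_gene_tree(sp_rooted, 1), simplify = FALSE)
  sp_u <- ape::unroot(sp_rooted); sp_u$edge.length <- NULL
  st <- score_rootings(sp_u, gts, sample_quintets(sp_u, "exhaustive"))
  expect_equal(nrow(st$table), 7)
  expect_equal(sort(st$table$rank), 1:7)
  # brute-force: cost of each of the 7 rooted quintets directly
  qd <- estimate_quintet_distribution(gts, letters[1:5])
  cat5 <- quintet_catalog(letters[1:5])
  idx <- quintet_topology_index(sp_u, cat5)
  rts <- quintet_rootings(cat5, idx)
  er <- enumerate_rootings(sp_u)
  brute <- vapply(er$edge_id, function(eid) {
    rooting_cost(quintet_order_structure(root_at_edge(sp_u, eid)), qd)
  }, numeric(1))
  got <- st$table$score[match(er$edge_id, st$table$edge_id)]
  expect_equal(unname(got), unname(brute), tolerance = 1e-12)
  # and the selected edge is the brute-force minimizer
  expect_equal(st$root_edge, er$edge_id[order(brute, er$edge_id)[1]])
})

test_that("scores are invariant to gene-tree order and to unusable trees", {
  set.seed(21)
  sp <- random_unrooted_tree(8, labels = letters[1:8])
  spr <- root_at_edge(sp, enumerate_rootings(sp)$edge_id[1])
  spr2 <- ape::compute.brlen(spr, 1)
  gts <- replicate(120, simulate_msc_gene_tree(spr2, 1), simplify = FALSE)
  plan <- sample_quintets(sp, "linear")
  s1 <- score_rootings(sp, gts, plan)
  s2 <- score_rootings(sp, rev(gts), plan)
  expect_equal(s1$table, s2$table)
  # trees that cannot display any resolved quintet leave scores unchanged
  fillers <- replicate(10, random_unrooted_tree(4, labels = letters[1:4]),
                       simplify = FALSE)
  s3 <- score_rootings(sp, c(gts, fillers), plan)
  expect_equal(s1$table$score, s3$table$score)
})

test_that("scoring fails explicitly when every quintet is uninformative", {
  set.seed(2)
  sp <- random_unrooted_tree(6, labels = letters[1:6])
  gts <- replicate(5, random_unrooted_tree(4, labels = letters[1:4]),
                   simplify = FALSE)
  expect_error(score_rootings(sp, gts), "no informative quintets")
})

test_that("linear sampling respects the preprocessing operation budget", {
  set.seed(100)
  sp <- random_unrooted_tree(12, labels = letters[1:12])
  spr <- ape::compute.brlen(root_at_edge(sp, enumerate_rootings(sp)$edge_id[3]), 1)
  gts <- replicate(60, simulate_msc_gene_tree(spr, 2), simplify = FALSE)
  st <- score_rootings(sp, gts, sample_quintets(sp, "linear"))
  n <- 12
  expect_lte(st$counters$cost_evaluations, 7 * (n - 3))
  # preprocessing work is linear in the number of gene trees
  st2 <- score_rootings(sp, c(gts, gts), sample_quintets(sp, "linear"))
  expect_equal(st2$counters$tree_quintet_scans,
               2 * st$counters$tree_quintet_scans)
  expect_equal(st2$counters$cost_evaluations, st$counters$cost_evaluations)
})

test_that("disco_qr equals the QR stage on single-copy inputs", {
  set.seed(64)
  sp_rooted <- parse_newick("((((a:1,b:1):0.8,c:1):0.8,d:1):0.8,e:1);")
  gts <- replicate(150, simulate_msc_gene_tree(sp_rooted, 1), simplify = FALSE)
  sp_u <- ape::unroot(sp_rooted); sp_u$edge.length <- NULL
  direct <- score_rootings(sp_u, gts, sample_quintets(sp_u, "exhaustive"))
  piped <- disco_qr(gts, sp_u, min_size = 4, mode = "exhaustive")
  expect_equal(piped$table$score, direct$table$score)
  expect_equal(piped$root_edge, direct$root_edge)
  expect_error(disco_qr(list(), sp_u), "no gene family trees")
})

test_that("exhaustive and linear sampling agree under strong signal", {
  set.seed(202)
  agree <- 0L
  for (rep in 1:5) {
    sp_rooted <- ape::rtree(7, tip.label = letters[1:7])
    sp_rooted <- ape::compute.brlen(sp_rooted, 1)  # informative ILS level
    gts <- replicate(8000, simulate_msc_gene_tree(sp_rooted, 1),
                     simplify = FALSE)
    sp_u <- ape::unroot(sp_rooted); sp_u$edge.length <- NULL
    e1 <- score_rootings(sp_u, gts, sample_quintets(sp_u, "exhaustive"))
    e2 <- score_rootings(sp_u, gts, sample_quintets(sp_u, "linear"))
    if (e1$root_edge == e2$root_edge) agree <- agree + 1L
  }
  expect_gte(agree, 4)
})
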