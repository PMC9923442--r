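test_that("species trees are ultrametric with the configured height", {
  set.seed(1)
  sp <- simulate_species_tree(21, tree_height = 2)
  expect_equal(ape::Ntip(sp), 21)
  expect_equal(sp$Nnode, 20)
  depths <- ape::node.depth.edgelength(sp)[1:21]
  expect_true(all(abs(depths - 2) < 1e-9))
  set.seed(99); a <- simulate_species_tree(10)
  set.seed(99); b <- simulate_species_tree(10)
  expect_identical(write_newick(a), write_newick(b))
})

test_that("zero duplication and loss reproduce the species tree per gene", {
  set.seed(2)
  sp <- simulate_species_tree(12)
  for (g in 1:10) {
    lt <- simulate_locus_tree(sp, 0, 0)
    expect_equal(ape::Ntip(lt), 12)
    ref <- sp; ref$tip.label <- paste0(ref$tip.label, "_1")
    expect_equal(rf_distance(ape::unroot(lt), ape::unroot(ref)), 0)
  }
})

test_that("duplication without loss keeps every species covered", {
  set.seed(3)
  sp <- simulate_species_tree(10)
  for (g in 1:15) {
    lt <- simulate_locus_tree(sp, 1, 0)
    spp <- map_species(lt$tip.label)
    expect_setequal(unique(spp), sp$tip.label)
    expect_gte(ape::Ntip(lt), 10)
  }
})

test_that("duplication counts match the birth-process expectation", {
  set.seed(4)
  sp <- simulate_species_tree(10)
  L <- sum(sp$edge.length)
  d <- 0.05
  n <- 600
  extra <- vapply(seq_len(n), function(i) {
    ape::Ntip(simulate_locus_tree(sp, d, 0)) - 10L
  }, integer(1))
  # with loss 0, each duplication adds one leaf; at small rates the
  # expected count per gene is close to d * total tree length
  expect_lt(abs(mean(extra) - d * L), 4 * stats::sd(extra) / sqrt(n) + 0.01)
})

test_that("gene trees preserve the locus leaf set and the no-ILS limit", {
  set.seed(5)
  sp <- simulate_species_tree(10)
  same <- 0L; total <- 0L
  for (g in 1:60) {
    lt <- simulate_locus_tree(sp, 0.5, 0.5)
    if (is.null(lt)) next
    total <- total + 1L
    gt <- simulate_msc_gene_tree(lt, 1000)
    expect_setequal(gt$tip.label, lt$tip.label)
    if (ape::Ntip(lt) < 4 ||
        rf_distance(ape::unroot(gt), ape::unroot(lt)) == 0) {
      same <- same + 1L
    }
  }
  expect_gte(same / total, 0.99)  # the no-ILS limit
  set.seed(77); g1 <- simulate_msc_gene_tree(sp, 1)
  set.seed(77); g2 <- simulate_msc_gene_tree(sp, 1)
  expect_identical(write_newick(g1), write_newick(g2))
})

test_that("quartet discordance follows the (2/3)exp(-t) law", {
  # species tree (((a,b):t,c):T,d) with T large: the only discordance
  # window is the branch of length t above the (a,b) ancestor
  t <- 0.5
  tr <- parse_newick(sprintf("(((a:1,b:1):%g,c:1):10,d:1);", t))
  set.seed(6)
  n <- 4000
  mismatch <- 0L
  for (i in seq_len(n)) {
    g <- simulate_msc_gene_tree(tr, 1)
    if (!"a|b" %in% tree_split_keys(ape::unroot(g))) mismatch <- mismatch + 1L
  }
  p <- (2 / 3) * exp(-t)
  expect_lt(abs(mismatch / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("NNI perturbation is identity at zero and grows with the dose", {
  set.seed(7)
  tr <- random_rooted_tree(21)
  expect_identical(perturb_gene_tree(tr, 0), tr)
  small <- parse_newick("((a,b),c);")
  expect_identical(perturb_gene_tree(small, 5), small)
  doses <- c(1, 4, 10, 25)
  mean_rf <- vapply(doses, function(ops) {
    mean(vapply(1:40, function(i) {
      normalized_rf(tr, perturb_gene_tree(tr, ops))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_rf) > -0.05))  # non-decreasing in expectation
  expect_setequal(perturb_gene_tree(tr, 3)$tip.label, tr$tip.label)
})

test_that("the NNI dose can be calibrated to 40% mean gene-tree error", {
  set.seed(8)
  trees <- replicate(25, random_rooted_tree(21), simplify = FALSE)
  ops <- calibrate_gtee_ops(trees, 0.40)
  set.seed(9)
  realized <- mean(vapply(trees, function(t) {
    normalized_rf(t, perturb_gene_tree(t, ops))
  }, numeric(1)))
  expect_lt(abs(realized - 0.40), 0.05)
})

test_that("AD is zero on identical inputs and decreases with ils_scale", {
  set.seed(10)
  sp <- simulate_species_tree(8)
  lts <- replicate(5, simulate_locus_tree(sp, 0.3, 0.3), simplify = FALSE)
  lts <- Filter(Negate(is.null), lts)
  expect_equal(as.numeric(average_distance(lts, lts)), 0)
  bad <- lts; bad[[1]] <- restrict_tree(bad[[1]],
                                        bad[[1]]$tip.label[-1])
  expect_error(average_distance(lts, bad), "gene 1")
  ads <- vapply(c(0.3, 1, 3, 10, 30), function(s) {
    cfg <- sim_config(n_species = 12, dup_rate = 0.3, ils_scale = s,
                      n_genes = 120, seed = 21)
    simulate_replicate(cfg)$ad
  }, numeric(1))
  expect_true(all(diff(ads) < 0))
})

test_that("replicates are reproducible and internally consistent", {
  cfg <- sim_config(n_species = 8, dup_rate = 0.8, ils_scale = 1,
                    n_genes = 25, seed = 33)
  r1 <- simulate_replicate(cfg)
  r2 <- simulate_replicate(cfg)
  expect_identical(vapply(r1$gene_trees, write_newick, ""),
                   vapply(r2$gene_trees, write_newick, ""))
  for (i in seq_along(r1$locus_trees)) {
    expect_setequal(r1$locus_trees[[i]]$tip.label,
                    r1$gene_trees[[i]]$tip.label)
  }
  g <- glance(r1)
  expect_equal(g$n_genes, length(r1$gene_trees))
  expect_true(g$ad >= 0 && g$ad <= 1)
})
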