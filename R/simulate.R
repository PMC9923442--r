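# Desk-scale simulator of the GDL + ILS generative process: a pure-birth
# species tree; locus trees from a duplication/loss birth-death walk of
# gene lineages down the species tree; gene trees from the multispecies
# coalescent within each locus tree; and random NNI moves standing in
# for gene-tree estimation error. Time is measured in units of the
# species-tree height; `ils_scale` converts time to coalescent units
# (small values = short coalescent branches = high ILS, playing the
# role of a large effective population size).

#' Simulation configuration
#'
#' @param n_species Number of species (>= 5).
#' @param speciation_rate Birth rate of the pure-birth species tree.
#' @param tree_height Root-to-tip height of the species tree (time
#'   units; all other rates are per unit of this clock).
#' @param dup_rate,loss_rate Duplication and loss rates per gene
#'   lineage per unit time (the study conditions use equal rates).
#' @param ils_scale Coalescent units per time unit. See
#'   [sim_presets()] for values calibrated to low (AD ~ 0.2) and high
#'   (AD ~ 0.64) ILS on 21-species trees.
#' @param n_genes Number of gene families per replicate.
#' @param gtee_ops Number of random NNI moves applied to each gene tree
#'   (0 = no estimation error; see [calibrate_gtee_ops()]).
#' @param on_extinct `"skip"` (drop and count gene families whose
#'   lineages all die) or `"resample"`.
#' @param seed Integer seed; identical configurations reproduce
#'   identical replicates.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 21, speciation_rate = 1, tree_height = 1,
                       dup_rate = 0.5, loss_rate = dup_rate,
                       ils_scale = 1, n_genes = 100, gtee_ops = 0,
                       on_extinct = c("skip", "resample"), seed = 1L) {
  on_extinct <- match.arg(on_extinct)
  stopifnot(n_species >= 5, speciation_rate > 0, tree_height > 0,
            dup_rate >= 0, loss_rate >= 0, ils_scale > 0, n_genes >= 1,
            gtee_ops >= 0)
  structure(list(n_species = n_species, speciation_rate = speciation_rate,
                 tree_height = tree_height, dup_rate = dup_rate,
                 loss_rate = loss_rate, ils_scale = ils_scale,
                 n_genes = n_genes, gtee_ops = gtee_ops,
                 on_extinct = on_extinct, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a rooted ultrametric species tree
#'
#' Pure-birth tree conditioned on the number of tips
#' ([ape::rphylo()]), rescaled to the configured height. Uses the
#' current RNG state; seed handling belongs to [simulate_replicate()].
#'
#' @param n_species Number of tips.
#' @param speciation_rate Birth rate.
#' @param tree_height Height after rescaling.
#' @return A rooted ultrametric `phylo` with tip labels `s01, s02, ...`.
#' @export
simulate_species_tree <- function(n_species, speciation_rate = 1,
                                  tree_height = 1) {
  tr <- ape::rphylo(n_species, birth = speciation_rate, death = 0)
  h <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * tree_height / h
  tr$tip.label <- sprintf("s%02d", seq_len(n_species))
  tr
}

# one gene lineage walking down the species tree from `node`, with
# `remaining` time left on the current species branch. Returns NULL
# (extinct) or list(len, type, species | children).
walk_lineage <- function(sp, node, remaining, dup_rate, loss_rate) {
  total <- dup_rate + loss_rate
  consumed <- 0
  repeat {
    if (total > 0) {
      tnext <- rexp(1, total)
      if (tnext < remaining) {
        consumed <- consumed + tnext
        remaining <- remaining - tnext
        if (runif(1) < loss_rate / total) return(NULL)
        a <- walk_lineage(sp, node, remaining, dup_rate, loss_rate)
        b <- walk_lineage(sp, node, remaining, dup_rate, loss_rate)
        if (is.null(a) && is.null(b)) return(NULL)
        if (is.null(a) || is.null(b)) {
          k <- if (is.null(a)) b else a
          k$len <- k$len + consumed
          return(k)
        }
        return(list(len = consumed, type = "dup", children = list(a, b)))
      }
    }
    # reached the end of the species branch without an event
    nt <- length(sp$tip.label)
    if (node <= nt) {
      return(list(len = consumed + remaining, type = "leaf",
                  species = sp$tip.label[node]))
    }
    kids <- sp$edge[sp$edge[, 1] == node, 2]
    lens <- sp$edge.length[match(kids, sp$edge[, 2])]
    sub <- vector("list", length(kids))
    for (i in seq_along(kids)) {
      sub[[i]] <- walk_lineage(sp, kids[i], lens[i], dup_rate, loss_rate)
    }
    sub <- Filter(Negate(is.null), sub)
    if (!length(sub)) return(NULL)
    if (length(sub) == 1L) {
      k <- sub[[1]]
      k$len <- k$len + consumed + remaining
      return(k)
    }
    return(list(len = consumed + remaining, type = "spec", children = sub))
  }
}

lineage_to_newick <- function(x, counter) {
  if (x$type == "leaf") {
    counter[[x$species]] <- (counter[[x$species]] %||% 0L) + 1L
    sprintf("%s_%d:%g", x$species, counter[[x$species]], x$len)
  } else {
    inner <- vapply(x$children, lineage_to_newick, character(1),
                    counter = counter)
    sprintf("(%s):%g", paste(inner, collapse = ","), x$len)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a locus tree by gene duplication and loss
#'
#' A birth-death walk of gene lineages down the species tree: starting
#' from one lineage at the root, each lineage independently duplicates
#' (both copies continue down the species tree from that point) and is
#' lost at the given per-time rates. Surviving copies at the species
#' tips become leaves labeled `species_copyindex`. Degree-2 nodes left
#' by losses are suppressed.
#'
#' @param species_tree Rooted ultrametric `phylo` with branch lengths.
#' @param dup_rate,loss_rate Events per gene lineage per unit time.
#' @return A rooted `phylo` (multi-copy when duplications survive),
#'   with branch lengths in time units, or `NULL` if fewer than two
#'   copies survive.
#' @export
simulate_locus_tree <- function(species_tree, dup_rate, loss_rate) {
  root <- length(species_tree$tip.label) + 1L
  res <- walk_lineage(species_tree, root, 0, dup_rate, loss_rate)
  if (is.null(res) || res$type == "leaf") return(NULL)
  counter <- new.env(parent = emptyenv())
  nwk <- lineage_to_newick(res, counter)
  # strip the stem length above the locus root
  nwk <- sub(":[0-9.eE+-]+$", "", nwk)
  parse_newick(paste0(nwk, ";"))
}

#' Simulate a gene tree under the multispecies coalescent
#'
#' One lineage per locus-tree leaf; within each locus branch, `k`
#' lineages coalesce at rate `k(k-1)/2` per coalescent unit (branch
#' lengths are time multiplied by `ils_scale`); lineages reaching the
#' locus root coalesce freely above it. The leaf set is preserved;
#' output branch lengths are in coalescent units.
#'
#' @param locus_tree Rooted `phylo` with branch lengths in time units.
#' @param ils_scale Coalescent units per time unit.
#' @return A rooted binary `phylo` on the same leaves.
#' @export
simulate_msc_gene_tree <- function(locus_tree, ils_scale) {
  stopifnot(ils_scale > 0)
  nt <- n_tips(locus_tree)
  if (nt < 2) return(locus_tree)
  M <- nt + locus_tree$Nnode
  depth <- ape::node.depth.edgelength(locus_tree)
  back <- (max(depth[seq_len(nt)]) - depth) * ils_scale
  parent <- rep(NA_integer_, M)
  parent[locus_tree$edge[, 2]] <- locus_tree$edge[, 1]
  pools <- vector("list", M)
  # lineage = list(nwk = subtree string, h = coalescent height of its root)
  for (i in seq_len(nt)) {
    pools[[i]] <- list(list(nwk = locus_tree$tip.label[i], h = back[i]))
  }
  post <- c(unique(ape::reorder.phylo(locus_tree, "postorder")$edge[, 2]),
            nt + 1L)
  post <- post[post > nt]
  kids <- split(locus_tree$edge[, 2], locus_tree$edge[, 1])
  for (v in post) {
    pool <- do.call(c, pools[kids[[as.character(v)]]])
    t <- back[v]
    end <- if (is.na(parent[v])) Inf else back[parent[v]]
    k <- length(pool)
    while (k > 1) {
      t <- t + rexp(1, k * (k - 1) / 2)
      if (t > end) break
      ij <- sample.int(k, 2)
      a <- pool[[ij[1]]]; b <- pool[[ij[2]]]
      merged <- list(
        nwk = sprintf("(%s:%g,%s:%g)", a$nwk, t - a$h, b$nwk, t - b$h),
        h = t)
      pool[[ij[1]]] <- merged
      pool <- pool[-ij[2]]
      k <- k - 1L
    }
    pools[[v]] <- pool
  }
  out <- pools[[nt + 1L]]
  stopifnot(length(out) == 1)
  parse_newick(paste0(out[[1]]$nwk, ";"))
}

#' Perturb a gene tree with random NNI moves
#'
#' Stand-in for gene-tree estimation error: applies `n_ops` random
#' nearest-neighbor interchanges ([phangorn::rNNI()]). The leaf set is
#' unchanged; trees with fewer than 4 leaves are returned as is.
#'
#' @param tree A `phylo`.
#' @param n_ops Number of NNI moves (>= 0).
#' @return A `phylo` on the same leaves.
#' @export
perturb_gene_tree <- function(tree, n_ops) {
  stopifnot(n_ops >= 0)
  if (n_ops == 0 || n_tips(tree) < 4) return(tree)
  out <- phangorn::rNNI(tree, moves = n_ops, n = 1)
  out
}

#' Average topological distance between locus trees and gene trees
#'
#' The ILS level statistic: the mean normalized Robinson-Foulds
#' distance between each locus tree (GDL only) and its gene tree (GDL
#' plus coalescent discordance), treating gene copies as distinct
#' leaves. Pairs with fewer than 4 leaves are skipped and counted in
#' the `n_skipped` attribute.
#'
#' @param locus_trees,gene_trees Paired lists of `phylo` objects with
#'   matching leaf sets.
#' @return Mean normalized RF in `[0, 1]`.
#' @export
average_distance <- function(locus_trees, gene_trees) {
  stopifnot(length(locus_trees) == length(gene_trees))
  vals <- numeric(0); skipped <- 0L
  for (i in seq_along(locus_trees)) {
    lt <- locus_trees[[i]]; gt <- gene_trees[[i]]
    if (is.null(lt) || is.null(gt)) { skipped <- skipped + 1L; next }
    if (!setequal(lt$tip.label, gt$tip.label)) {
      abort(sprintf("gene %d: locus and gene tree leaf sets differ", i))
    }
    if (n_tips(lt) < 4) { skipped <- skipped + 1L; next }
    vals <- c(vals, normalized_rf(lt, gt))
  }
  structure(mean(vals), n_skipped = skipped)
}

#' Simulate one replicate of the GDL + ILS study conditions
#'
#' @param cfg A [sim_config()].
#' @return An object of class `sim_replicate`: `species_tree` (rooted),
#'   `locus_trees`, `gene_trees`, `perturbed_trees` (parallel lists),
#'   realized `ad` (locus-vs-gene normalized RF, the ILS statistic),
#'   `mgte` (gene-vs-perturbed normalized RF), and `n_dropped` (gene
#'   families extinct or reduced below two copies).
#' @export
simulate_replicate <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  sp <- simulate_species_tree(cfg$n_species, cfg$speciation_rate,
                              cfg$tree_height)
  locus <- list(); genes <- list(); pert <- list()
  n_dropped <- 0L
  for (g in seq_len(cfg$n_genes)) {
    lt <- simulate_locus_tree(sp, cfg$dup_rate, cfg$loss_rate)
    if (is.null(lt)) {
      n_dropped <- n_dropped + 1L
      if (cfg$on_extinct == "skip") next
      tries <- 0L
      while (is.null(lt)) {
        tries <- tries + 1L
        if (tries > 1000L) {
          abort("almost all gene families go extinct under these rates")
        }
        lt <- simulate_locus_tree(sp, cfg$dup_rate, cfg$loss_rate)
        if (is.null(lt)) n_dropped <- n_dropped + 1L
      }
    }
    gt <- simulate_msc_gene_tree(lt, cfg$ils_scale)
    locus[[length(locus) + 1L]] <- lt
    genes[[length(genes) + 1L]] <- gt
    pert[[length(pert) + 1L]] <- perturb_gene_tree(gt, cfg$gtee_ops)
  }
  ad <- if (length(locus)) average_distance(locus, genes) else NA_real_
  mgte <- if (length(genes)) average_distance(genes, pert) else NA_real_
  structure(list(config = cfg, species_tree = sp, locus_trees = locus,
                 gene_trees = genes, perturbed_trees = pert,
                 ad = as.numeric(ad), mgte = as.numeric(mgte),
                 n_dropped = n_dropped),
            class = "sim_replicate")
}

#' @export
print.sim_replicate <- function(x, ...) {
  cat("Simulated replicate:", length(x$gene_trees), "gene families on",
      x$config$n_species, "species\n")
  cat("  AD (ILS level):", round(x$ad, 3),
      " MGTE proxy:", round(x$mgte, 3),
      " dropped families:", x$n_dropped, "\n")
  invisible(x)
}

#' @export
glance.sim_replicate <- function(x, ...) {
  nl <- vapply(x$locus_trees, n_tips, integer(1))
  tibble::tibble(
    n_species = x$config$n_species,
    n_genes = length(x$gene_trees),
    n_dropped = x$n_dropped,
    ad = x$ad,
    mgte = x$mgte,
    mean_copies = mean(nl) / x$config$n_species,
    max_leaves = max(nl)
  )
}

# ---------------------------------------------------------------------------

#' Calibrate the ILS scale to a target AD
#'
#' AD (mean locus-vs-gene normalized RF) decreases monotonically in
#' `ils_scale`; this bisects on the log scale until the realized AD on
#' small calibration replicates matches the target.
#'
#' @param target_ad Target AD in (0, 1).
#' @param cfg Base configuration (its `ils_scale` is ignored).
#' @param n_genes Genes per calibration replicate.
#' @param n_reps Replicates (fresh species trees) averaged per
#'   evaluation; AD varies substantially between species trees, so the
#'   target is a cross-replicate mean.
#' @param iterations Bisection steps.
#' @return The calibrated `ils_scale`.
#' @export
calibrate_ils_scale <- function(target_ad, cfg = sim_config(),
                                n_genes = 200, n_reps = 4, iterations = 10) {
  f <- function(scale) {
    mean(vapply(seq_len(n_reps), function(r) {
      c2 <- cfg; c2$ils_scale <- scale; c2$n_genes <- n_genes
      c2$gtee_ops <- 0
      c2$seed <- cfg$seed + r - 1L
      simulate_replicate(c2)$ad
    }, numeric(1)))
  }
  lo <- 1e-3; hi <- 1e3   # AD(lo) high, AD(hi) ~ 0
  for (i in seq_len(iterations)) {
    mid <- sqrt(lo * hi)
    if (f(mid) > target_ad) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Calibrate the NNI count to a target mean gene-tree error
#'
#' @param trees Example gene trees (e.g. one replicate's gene trees).
#' @param target_nrf Target mean normalized RF between original and
#'   perturbed trees (e.g. 0.4 for moderate estimation error).
#' @param max_ops Largest NNI count tried.
#' @return The `n_ops` whose realized mean normalized RF is closest to
#'   the target.
#' @export
calibrate_gtee_ops <- function(trees, target_nrf, max_ops = 40) {
  trees <- Filter(function(t) n_tips(t) >= 4, trees)
  best <- 1L; bestgap <- Inf
  for (ops in seq_len(max_ops)) {
    nrf <- mean(vapply(trees, function(t) {
      normalized_rf(t, perturb_gene_tree(t, ops))
    }, numeric(1)))
    gap <- abs(nrf - target_nrf)
    if (gap < bestgap) { bestgap <- gap; best <- ops }
    if (nrf > target_nrf + 0.1) break
  }
  best
}

#' Calibrated study-condition presets (21 species)
#'
#' ILS scales calibrated once with [calibrate_ils_scale()] so that the
#' realized AD on 21-species pure-birth trees is approximately 0.2
#' (low ILS) and 0.64 (high ILS); see the methods vignette.
#'
#' @return A tibble of named conditions with `ils_scale` and target AD.
#' @export
sim_presets <- function() {
  tibble::tibble(
    condition = c("low_ils", "high_ils"),
    target_ad = c(0.20, 0.64),
    ils_scale = c(14, 2.43)
  )
}
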