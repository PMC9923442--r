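---
title: "Rooting species trees from gene family trees: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rooting species trees from gene family trees: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(multiroot)
```

This vignette is the package's account of its science: the generative
model it assumes, the two-stage rooting method, the empirically derived
quintet order structures at its core, the synthetic-data generator used
to validate it, and the design decisions taken where the design was
genuinely open.

## The problem and the model

A species tree relates a set of species; a *gene family tree* relates
the copies of one gene found in those species. Two processes make gene
family trees disagree with the species tree:

* **Gene duplication and loss (GDL).** Along each species-tree branch,
  a gene lineage may duplicate (both copies continue evolving down the
  tree) or be lost. Surviving copies make the gene tree *multi-copy*
  (a MUL-tree): several leaves can map to one species, and species can
  be missing entirely.
* **Incomplete lineage sorting (ILS).** Even for a single-copy locus,
  ancestral polymorphism makes the gene tree topology a random draw
  from the multispecies coalescent (MSC): within a species-tree branch
  of length $t$ coalescent units, $k$ gene lineages coalesce at rate
  $k(k-1)/2$, and lineages reaching the root coalesce freely in the
  unbounded root branch.

Unrooted species-tree topology estimation from such data is well
served by existing methods; this package addresses the *rooting* of a
given unrooted species tree. The key fact is that ILS is informative
about the root: the distribution of *unrooted* gene-tree topologies on
any five species depends on the *rooted* 5-taxon species tree, and
satisfies equalities and inequalities sufficient to identify it. (Four
taxa are not enough — the unrooted quartet distribution is
root-invariant — which is why quintets are the unit of analysis and
why `score_rootings()` requires at least five species.)

## Stage 1: decomposition into single-copy trees

ILS-based rooting needs single-copy gene trees, so multi-copy trees
are first decomposed:

1. **Root-and-tag.** For each unrooted gene family tree, every rooting
   (one per edge) implies a tagging of internal nodes: a node is a
   *duplication* iff the species sets of two of its children intersect
   (`tag_gene_tree()`). `optimal_root()` selects the rooting minimizing
   the pair (number of duplications, loss surrogate) lexicographically.
   The loss surrogate is $\sum_{\text{dup } v} |S_L(v)\,\Delta\,S_R(v)|$,
   the number of species under exactly one child of each duplication —
   a species-tree-free lower-bound stand-in used only as a tie-breaker,
   since true loss counting would require reconciliation against the
   species tree being rooted. Remaining ties go to the smallest
   canonical edge identifier.
2. **Decompose.** Duplication nodes are processed bottom-up; at each
   one the child subtree covering fewer distinct species is detached
   and emitted (ties: fewer leaves, then keep the side holding the
   lexicographically smallest label), keeping one large subtree
   growing. Emitted pieces partition the input leaves; pieces smaller
   than `min_size` (default 4 — smaller trees cannot display a
   quintet) are dropped and counted.

`optimal_root()` evaluates all rootings incrementally: directional
species sets are computed once, and a depth-first walk over the edges
updates the single node whose orientation changes between adjacent
rootings. The quadratic reference — tag every rooting from scratch —
defines correctness and is the oracle in the test suite.

## Stage 2: quintet rooting

For a quintet $q$ (five species), the estimated distribution
$\hat u \in \Delta^{14}$ counts, over single-copy trees containing all
of $q$, which of the 15 unrooted quintet topologies the tree induces
on $q$ (unresolved restrictions are discarded; the count of
contributing trees is the quintet's support $m$).

Each of the 7 rootings of the species tree's induced quintet topology
has an *order structure*: a set $E$ of index pairs whose true
probabilities are equal, and a set $G$ of ordered pairs $(i,j)$ with
$p_i > p_j$, valid for all branch lengths. The cost of a rooted
quintet against $\hat u$ is

$$\mathrm{cost}(R, \hat u) \;=\; \frac{1}{|E_R|}\sum_{(i,j)\in E_R} |\hat u_i - \hat u_j|
\;+\; \frac{1}{|G_R|}\sum_{(i,j)\in G_R} \max(0,\, \hat u_j - \hat u_i),$$

zero exactly when every equality holds and no ordering is violated.
The score of a candidate root edge of the full species tree is the sum
of the costs of the rooted quintets it induces; all $2n-3$ edges are
scored and ranked, and exact ties are broken by the smallest canonical
edge identifier and reported as ties.

**Why class means rather than sums.** The three rooted 5-leaf shapes
have different numbers of equality pairs. With summed penalties, a
rooting whose structure has few equality pairs enjoys a smaller
sampling-noise floor ($\mathbb{E}\sum_E |\text{noise}| \propto |E|/\sqrt m$),
which we measured as a persistent bias toward constraint-poor rootings
that more gene trees cannot remove. Averaging within each class
equalizes the floors; the decisive differences between rootings then
come from violated constraints, which is what the theory identifies
the root by.

### Deriving the order structures

Rather than transcribing the known algebraic results, the structures
are derived from the package's own MSC oracle
(`msc_quintet_probs()`, a compiled Monte-Carlo sampler), which makes
their provenance verifiable inside the package. For each of the three
rooted shapes, 100 random branch-length vectors are drawn uniformly
from $[0.05, 2]$ coalescent units per internal branch (strong to weak
ILS, avoiding zero-information degenerate lengths), and each candidate
pair is classified from the $15 \times 100$ probability table
($1.5\times 10^5$ samples per draw):

* **equality** if the two components are within 4 Monte-Carlo standard
  errors in *every* draw;
* **order $i > j$** if the difference is never significantly reversed
  (above $-4$ SE everywhere) and significantly positive (above $+5$
  SE) in at least one draw;
* **omitted** otherwise — in particular pairs whose true order flips
  with branch lengths.

The one-sided order rule is essential. Several root-identifying
inequalities hold strictly for all branch lengths but with margins
that vanish as branches lengthen (e.g. $p(ab|cd,e) > p(ab|ce,d)$ under
the caterpillar $((((a,b),c),d),e)$); demanding significance in every
draw prunes exactly these, after which even exact probabilities cannot
separate the true rooting from two rivals. The thresholds (4 and 5 SE)
control the familywise error of the $105 \times 100$ comparisons per
shape at well below one misclassified pair per derivation.

Two corrections are applied before caching. First, the structure is
symmetrized over the shape's automorphism group (within-cherry swaps,
and the cherry exchange of the pseudo-caterpillar): the model
structure is exactly automorphism-invariant, while Monte-Carlo
verdicts on a pair and its mirror get independent noise; intersecting
verdicts over each orbit restores exact invariance, which in turn
makes structures exactly permutation-covariant across labelings.
Second, derivation happens once per shape (fixed internal seeds) and
every labeled rooted quintet receives the representative's structure
through the induced permutation of topology indices, so the pipeline
never re-derives. `write_order_structures()` /
`read_order_structures()` persist the tables as TSV.

**The anomaly zone.** The derived caterpillar structure does *not*
order the matching topology above the two-cherries topology
$((a,b),(c,d),e)$, and that is correct: caterpillar species trees with
both lower internal branches short and the top branch long produce
*anomalous gene trees* — in the star-tree limit the two-cherries
topology reaches probability $1/9$ against the matching topology's
$1/18$. The pair is order-flipping, is omitted, and contributes no
cost. Identifiability does not suffer: it rests on the remaining 94
relations per shape.

## The synthetic-data generator

`simulate_replicate()` emulates the generative model at desk scale:

* **Species tree:** pure-birth tree conditioned on `n_species` tips
  (`ape::rphylo`), rescaled to height 1 time unit. All rates are per
  unit of this clock.
* **Locus trees:** one gene lineage enters at the root; along each
  species branch every lineage independently duplicates
  (rate `dup_rate`) — both copies continuing down the species tree —
  or dies (rate `loss_rate`). Equal rates are the study condition;
  `dup_rate = 0.5` per unit height is the package's moderate GDL
  regime (about 1.2 copies per species on 21-species trees, with
  occasional large families). Families reduced below two surviving
  copies are dropped and counted (`on_extinct = "skip"` by default).
* **Gene trees:** the MSC runs inside each locus tree with branch
  lengths multiplied by `ils_scale` (coalescent units per time unit);
  coalescence between paralogous copies beyond the locus-tree
  structure (the full joint model's bounded coalescence) is ignored, a
  standard simplification — discordance levels remain controllable.
* **Estimation error:** `gtee_ops` random NNI moves per gene tree, a
  topological stand-in for sequence simulation plus maximum-likelihood
  gene-tree estimation. `calibrate_gtee_ops()` finds the dose hitting
  a target mean normalized RF (0.4 reproduces "moderate" error).

The ILS level is reported as **AD** — the mean normalized
Robinson–Foulds distance between each locus tree and its gene tree —
and controlled through `ils_scale`, which plays the role of the
effective population size. Because AD varies substantially between
random species trees, `calibrate_ils_scale()` bisects on the
cross-replicate *mean* AD. The shipped presets (`sim_presets()`),
calibrated once on 21-species trees at the moderate GDL regime, are
`ils_scale = 2.43` for AD $\approx 0.64$ (high ILS) and `14` for AD
$\approx 0.20$ (low ILS); both were verified on fresh seeds before
freezing.

What the generator does *not* emulate: sequence evolution and
alignment (hence its "estimation error" is topological and
rate-homogeneous), branch-rate heterogeneity, gene conversion and
transfer, and hemiplasy between duplicate copies. Passing tests on
this generator therefore demonstrate correctness of the method under
its own model assumptions, not robustness to everything real data do.

## Evaluation metrics

`ncd()` implements the normalized clade distance
$\bigl(|C(R^*)\setminus C(R)| + |C(R)\setminus C(R^*)|\bigr)/(2n-4)$
over *proper nontrivial* clades (singletons and the full leaf set are
excluded — with this convention the denominator $2n-4$ is exactly the
maximum for binary trees and nCD lies in $[0,1]$). When the two trees
share an unrooted topology, the symmetric difference is exactly twice
the number of edges between the two root positions, which `ncd()`
also reports and asserts. `expected_random_ncd()` averages nCD over
all $2n-3$ rootings — the chance baseline a method must beat.

## Numerical choices and degenerate inputs

* Branch lengths are parsed and preserved but ignored by all rooting
  computations; the method is topology-only.
* Species-tree inputs must be binary; gene trees may contain
  polytomies (tagging treats a node as a duplication if *any* two
  children's species sets intersect; unresolved quintet restrictions
  are discarded).
* Quintets with zero support are skipped; if every quintet has zero
  support, `score_rootings()` fails explicitly rather than returning
  an arbitrary root. Gene-tree species absent from the species tree
  are pruned with a warning.
* Exact score ties are broken by the smallest canonical edge
  identifier and flagged in the output table.
* Gene-copy labels map to species by the `SPECIES_copyid` underscore
  convention by default, or by an explicit two-column table.
* All stochastic steps are reproducible: simulation configurations
  carry seeds, sampling plans carry seeds, and the Monte-Carlo oracle
  takes one.

## Problem sizes used in validation

The test suite validates the statistical claims at sizes a desk
machine handles comfortably: the 5-taxon consistency check uses 20
replicates of 10,000 gene trees (internal branches 0.5 coalescent
units); the end-to-end check uses 10 replicates of the 21-species
high-ILS condition with 1000 gene families each (also evaluated at 100
families for the gene-number trend), compared against the exact
random-rooting baseline; exhaustive-vs-linear sampling agreement is
checked on 7-taxon trees with 8000 gene trees. The operation-count
contract of linear sampling (at most $7(n-3)$ per-quintet cost
evaluations, preprocessing linear in the number of gene trees) is
asserted on counters, not wall time.

## Known limitations

* The linear-encoding edge-to-quintet map (smallest leaf in each of
  the four subtrees around an edge, plus the smallest unused leaf from
  the largest) is this package's deterministic realization of "one
  quintet per edge"; other choices are possible and exhaustive
  sampling remains the reference.
* The loss surrogate in rooting gene family trees is a lower-bound
  proxy, not reconciliation-based loss counting.
* Order structures are empirical: pairs are occasionally omitted that
  algebra would resolve, costing a little statistical efficiency,
  never correctness of the zero-cost property.
* With few informative quintets or shallow support, near-ties between
  edges adjacent to the true root are common; the ranked table and
  `evaluate_rooting()`'s rank curve are the honest summary in that
  regime.
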