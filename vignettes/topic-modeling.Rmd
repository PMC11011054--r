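---
title: "Block-model topic modeling of single-cell multi-omics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block-model topic modeling of single-cell multi-omics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sctopics)
library(dplyr)
```

## The model

`sctopics` phrases single-cell clustering as community detection on a
weighted multigraph. Every gene of every layer and every cell is a node;
a count of `w` for gene `g` in cell `c` becomes `w` parallel edges
between the two nodes. Genes never connect to genes, so one layer gives a
bipartite network and two layers (e.g. protein-coding mRNAs and lncRNAs
quantified on the same cells) give a tripartite one with the cells
shared. Fitting a degree-corrected stochastic block model to this network
groups cells into *clusters* and genes into *topics* simultaneously; the
degree correction is essential because sequencing depth and gene
expression level vary over orders of magnitude and would otherwise
dominate the partition.

The fit minimizes the description length `Sigma = -ln[P(A|M) P(M)]`, the
number of nats the model needs to describe the data. The likelihood part
is the microcanonical degree-corrected multigraph entropy

$$ S = -E - \sum_v \ln k_v! - \tfrac12 \sum_{rs} e_{rs}
   \ln\!\frac{e_{rs}}{e_r e_s}, $$

where `E` is the total edge multiplicity, `k_v` node degrees, `e_rs` the
edge count between blocks `r` and `s` and `e_r` the block degree; terms
with `e_rs = 0` contribute nothing, and because the graph is multipartite
the diagonal is always empty. The prior `-ln P(M)` adds, per node type, a
uniform partition prior (`ln C(N-1, B-1) + ln N! - sum_r ln n_r! + ln N`),
a uniform degree-sequence prior per block (`ln ((n_r, e_r))`, a multiset
coefficient), and a flat prior over block-level edge matrices
(`ln ((P, E))` with `P` the number of block pairs allowed by the type
structure). The exact constants live in `src/sbm.cpp` next to the code
that maintains them; the test suite pins the incremental bookkeeping to a
from-scratch recomputation to `1e-9` nats rather than pinning individual
constants. Two consequences worth knowing: `Sigma` is finite for every
valid typed partition, and on dense multigraphs the Stirling-form entropy
can be negative — only differences in `Sigma` matter.

## Inference

Nodes move between blocks by MCMC. A proposal for node `v` samples one of
its edges uniformly, looks up the block `t` of the opposite endpoint, and
draws a target block `s` from

$$ \Pr(s \mid t) = \frac{e_{ts} + \epsilon}{e_t^{(\tau)} + \epsilon B}, $$

where `tau` is `v`'s node type, `e_t^{(tau)}` counts the edges between
`t` and nodes of that type, and `B` counts the candidates — the existing
blocks of type `tau` plus one fresh empty block, so the number of blocks
can grow as well as shrink. With no connections between the blocks the
kernel degenerates to the uniform distribution. Restricting `e_t` to the
moving type is what makes the kernel normalize on tripartite graphs; on
bipartite graphs it equals the plain block degree. This edge-guided
kernel alone cannot minimize `Sigma`, so it is used as the *proposal* of
a Metropolis–Hastings step: a move is accepted with probability
`min(1, exp(-beta * dSigma) * p(reverse)/p(forward))`, with the proposal
probabilities marginalized over the sampled neighbour block. For cells in
a multipartite fit the sampled edge decides which layer the proposal
looks at, so each omics layer acts through its own edge counts and no
cross-layer normalization is ever needed.

One fit runs `n_init` independent initializations (default 7, the point
where additional starts stopped improving the reached minimum in our
calibration runs). Each initialization starts from a random typed
partition (about `sqrt(N)` blocks per type, varied across starts), runs
MH sweeps at `beta = 1` until the best `Sigma` seen has not improved by
more than `tol = 1e-6` nats for `patience = 10` sweeps (hard cap 1000),
restores the best partition, and polishes it with greedy sweeps
(accepting only improvements) plus greedy pairwise block merges. The
initialization with the smallest `Sigma` wins; ties in randomness are
impossible because every random stream (initial partitions, sweep order,
proposals) derives deterministically from the master seed, making fits
bit-reproducible.

The hierarchy is agglomerative: the best partition's block multigraph
(nodes = blocks, edge weights = `e_rs`) is itself fitted, recursively,
until one block per type remains. Each level therefore coarsens the one
below — the refinement invariant the tests check. When a block-level fit
declines to merge anything but more than one block per type remains, the
single merge with the smallest `Sigma` increase is forced so the
recursion always terminates; this can produce runs of near-identical
levels, which is harmless because analyses select levels by content (see
below), not by index.

## Probability tables and topic assignment

All quantities downstream of the fit are exact functions of the graph and
a partition, with no hidden state:

* `P(gene | topic) = k_gene / e_topic` within each topic (degree
  fractions; columns sum to 1);
* `P(topic | cell) = e(cell, topic) / k_cell^(layer)` with the cell degree
  restricted to the topic's layer, so each layer's row normalizes to 1 on
  its own. (Read as printed elsewhere this ratio is sometimes inverted;
  only this direction normalizes, so it is the one implemented.)

Topic-to-cluster assignment centers `P(topic | cell)` by subtracting each
topic's mean across cells, averages the centered values within clusters,
and assigns to cluster `K` every topic with
`Pc(T|K) > mu_K + n * sigma_K`. `mu_K` and `sigma_K` are the mean and
*population* (divide-by-N) standard deviation across topics — the
convention chosen here since either is defensible; with both layers'
topics concatenated, `mu` and `sigma` pool the layers, mirroring how the
assignment is read off a joint heatmap. `n` starts at 3 and is lowered in
steps of 0.05 until every cluster has a topic and no two clusters carry
identical sets (subsets allowed). Thresholds only loosen as `n` falls, so
topic sets grow monotonically and the first feasible `n` is final. If
even `n = 0` fails — for instance two clusters with identical centered
profiles — the function errors and names the offending clusters rather
than silently falling back to argmax topics: a degenerate partition is
something the analyst should see. The same operation applies to any cell
partition (e.g. known subtype labels), not just the model's own clusters.

## Scoring

`nmi()` normalizes mutual information by the arithmetic mean of the two
entropies (the `normalization` argument exposes min/max/sqrt variants),
with NMI defined as 0 when either partition has a single cluster so the
null model below stays finite. Because NMI inflates with the number of
clusters, `nmi_null()` estimates `NMI*`, the mean NMI of size-preserving
random relabelings (default 100 shuffles, mean aggregation; both
overridable), and `clustering_score()` reports `NMI/NMI*` — how far the
clustering sits above its own chance level. `ami()` implements adjusted
mutual information under the permutation model for comparing two
clusterings when neither is ground truth; the tests pin it to a reference
implementation to `1e-9`.

## Enrichment

Topic gene lists need no p-value cutoff — the block model defines them.
Each topic is tested against a GMT collection by the hypergeometric upper
tail `P(X >= k)`, with BH correction across all tests of a collection.
Two design choices the databases force: first, sets larger than 15% of
their collection's gene universe are filtered out beforehand (large
catch-all sets otherwise dominate every test; within a collection set
size tracks redundancy closely enough that this ratio filter approximates
a pairwise Jaccard filter at negligible cost). Second, the test universe
defaults to the intersection of the analyzed feature list with the
collection's gene union, the least arbitrary background available when
the data and the database cover different gene catalogs. Each assigned
topic is labeled with its lowest-q set; a set claimed by several topics
stays with the lowest-q topic and the others fall back to their next-best
set, with ties broken by overlap then name so the labeling is
deterministic.

## The synthetic-data generator

`simulate_layers()` emulates the structure of a paired-subtype,
sensitive/resistant tumor single-cell experiment: four cell groups (2
subtypes × sensitive/resistant, 50 cells each by default), an mRNA-like
layer of 200 genes and a noisier lncRNA-like layer of 150 genes over the
same cells. Each layer has 4 topics owning disjoint gene slices with
Dirichlet-weighted gene probabilities; a cell's topic weights are its
group's affinity row; counts are multinomial draws at a uniform random
depth (1000–2000 for layer 1, 300–800 for layer 2). Layer 2 multiplies
its per-cell gene rates by gamma noise with `shape = 1/dispersion`
(dispersions 0.05 vs 0.6), reproducing the empirically higher coefficient
of variation of lncRNAs — the tests verify the CV ordering across seeds.

The affinities encode *complementary* signal: both layers separate the
subtypes strongly, but layer 1 resolves the sensitive/resistant split
only within the second subtype and layer 2 only within the first. Either
layer alone can therefore recover at most three of the four groups while
the tripartite fit can recover all four — the cleanest construction that
makes integration demonstrably useful. (An earlier design gave layer 1 a
uniformly "weak" resistance signal, but at any strength the block model
either detects it in both subtypes or in neither, which makes single-layer
fits either complete or uninformative; the complementary design pins the
intended behaviour robustly.) Effect sizes are deliberately strong:
recovery should be limited by the method, not by an underpowered
simulation, and a full tripartite fit plus both single-layer fits runs in
a few seconds.

What the generator does *not* emulate: ambient RNA, doublets, batch
effects, zero-inflation beyond what the multinomial sparsity produces,
and realistic gene-count scales (hundreds of genes, not tens of
thousands). Passing tests demonstrate correctness of the machinery and
recoverability of planted structure at these scales — not performance on
any particular real dataset.

## Numerical choices and scales

* Incremental `Sigma` bookkeeping is pinned to full recomputation within
  `1e-9` nats after 1000 arbitrary moves; states resynchronize after each
  optimization phase so drift cannot accumulate across a fit.
* Probability-table normalizations hold to `1e-12`; written TSV tables
  round-trip to the same tolerance.
* The adaptive-threshold grid appends an exact 0 endpoint so floating
  error in `seq()` cannot skip the last feasible multiplier; strict
  inequality is used at the threshold, as specified.
* Degenerate inputs fail loudly: all-zero layers, empty universes,
  duplicate identifiers, clusters with identical centered profiles, and
  mismatched cell lists all raise errors rather than warnings.
* Problem sizes in the tests and the acceptance script — 200 cells × 100
  genes for planted recovery (20 seeds), 200 cells × 350 genes for the
  three-way integration comparison (20 seeds × 3 fits), `1e5` kernel
  draws × 10 states — keep the full suite in the low minutes on a single
  CPU while leaving each check comfortably powered.
* "Level-appropriate" partitions for comparisons against known groups are
  chosen by one fixed rule: the hierarchy level whose cell-cluster count
  is closest to the number of known groups, ties resolved toward the
  finer level.

## Known limitations

* Hard (non-overlapping) blocks only; no mixed membership.
* The agglomerative hierarchy is greedy; levels between the finest and
  coarsest are locally, not globally, optimal, and duplicate levels can
  appear where forced merges were needed.
* No parity with any external SBM implementation is attempted: prior
  constants differ between implementations, so `Sigma` values are
  comparable only within this package.
* Enrichment supports one collection at a time; cross-collection
  summaries concatenate results before `summarize_topic_annotations()`.

## A minimal end-to-end run

```{r example, eval = FALSE}
sim <- simulate_layers(seed = 7)
run <- run_topic_model(list(sim$layer1, sim$layer2),
                       min_disp = -Inf,   # synthetic genes are all informative
                       n_init = 7, seed = 7)
lev <- closest_level(run$fit, 4)
cc <- inner_join(cell_clusters(run$fit, lev), sim$cell_groups, by = "cell")
clustering_score(cc$cluster, cc$group, n_shuffles = 100, seed = 1)
assign_topics(run$fit, level = lev)
```
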