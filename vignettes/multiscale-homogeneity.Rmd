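---
title: "Multi-scale community detection and the interaction-controlled homogeneity test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale community detection and the interaction-controlled homogeneity test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pottsnet)
```

# The model

`pottsnet` treats community detection in a protein interaction network as
minimisation of a Potts energy over node-to-community assignments $s$:

$$H(s; \lambda) \;=\; -\sum_{i \neq j}
  \Big(B_{ij} - \lambda\,\frac{k_i k_j}{2W}\Big)\,\delta(s_i, s_j),$$

summed over ordered pairs of distinct nodes. $B$ is the (binary,
undirected) adjacency matrix, $k_i$ the degree, $W$ the number of edges,
and the null term $k_ik_j/2W$ is the Newman–Girvan configuration-model
expectation, which preserves the expected degree sequence. The resolution
parameter $\lambda$ tilts the balance: at $\lambda = 1$, $H$ is $-2W$
times standard modularity; as $\lambda \to 0$ any connected network
collapses into a single community, and once
$\lambda > \max_{(i,j)\in E} 2W/(k_ik_j)$ every pairwise coupling is
negative and the all-singletons partition is optimal
(`singleton_lambda_bound()`). Sweeping $\lambda$ over
$-1 \le \log_{10}\lambda \le 3$ therefore interpolates from the whole
network down to trivial fragments, passing through every intermediate
scale.

Two conventions are fixed here and matter for exact values, not optima:

* **Ordered distinct pairs.** Summing over ordered pairs doubles $H$
  relative to an unordered-pair convention; any such constant factor
  rescales every partition's energy equally. Worked value: the triangle
  $K_3$ as one community at $\lambda = 1$ has
  $H = -6(1 - \tfrac{2}{3}) = -2$.
* **Self-loops are dropped** before detection. A self-pair's
  contribution $\delta(s_i,s_i) = 1$ is identical in every partition, so
  removal cannot change any argmin; self-loops are still counted in
  network summary statistics (once as an edge, twice in degree).

## Optimisation

$H$ is minimised with a seeded Louvain-style two-phase greedy: repeated
single-node moves to the neighbouring (or a fresh singleton) community
with the largest strict energy decrease, then aggregation of communities
into super-nodes, iterated to convergence. The inner move loop is
compiled (Rcpp); the node visit order is a Fisher–Yates shuffle from a
`mt19937` stream seeded by the user, so results are bit-reproducible
across runs and platforms. Ties among equally improving moves go to the
lowest community label.

Like every greedy modularity-type optimiser this finds a local optimum,
and near-optimal partitions are massively degenerate. The package's tests
therefore compare *energies* and *recovered planted structure* (via
normalised mutual information), never exact label sets, except on tiny
fixtures where exhaustive enumeration over all set partitions provides
the true minimum (two bridged triangles, two bridged 4-cliques).

Within a sweep, each grid point can warm-start from the previous
$\lambda$'s partition (the default; roughly halves runtime) or run
independently from singletons (`warm_start = FALSE`). The two modes can
settle in different local optima near split points — a warm start refines
by single-node moves and occasionally lags one grid step behind a clean
split; both modes are exposed, and the recovery tests pass in the default
mode.

## Community identity across resolutions

To speak of "the same community" at two resolutions, adjacent partitions
are matched by node overlap: for community $K_i$ at the higher resolution
and $L_j$ at the lower, the score is the Jaccard index
$W_{ij} = |K_i \cap L_j| / |K_i \cup L_j|$. Matching is greedy in
decreasing $W_{ij}$, each community used at most once (ties: larger
intersection, then lower old label); when the higher-resolution partition
has more communities, the unmatched ones get fresh labels. Applied
sequentially from the coarse end of the grid, a label introduced when a
community first splits off persists as long as its community does — the
direction that makes the pairwise rule globally consistent. A
raw-intersection variant (`overlap = "intersection"`, a link-style
convention) is provided and gives near-identical labellings. Relabelling
only renames: co-clustering at every grid point is untouched, which is
tested as an invariant.

# Pairwise functional similarity

Three measures, one contract: a symmetric value per interacting pair,
higher meaning more functionally alike.

* **Rarity of the shared annotation set (`G`).** Annotations are first
  propagated up the ontology (ancestral closure, root excluded; a
  root-only protein counts as unannotated). For a pair, $n_{ij}$ counts
  proteins whose propagated set contains the pair's shared set; an empty
  shared set is vacuously shared by all $N$. The default functional form
  is $G_{ij} = 1 - n_{ij}/N$: decreasing in $n_{ij}$, zero for vacuous
  sharing, and never penalising missing annotation below zero. The form
  is a pluggable function — any monotone decreasing alternative yields
  the same homogeneity ordering after re-standardisation, because the
  z-test is invariant to monotone rescaling up to the induced change in
  $\mu$ and $\sigma$.
* **Flat-vocabulary rarity (`M`).** The same formula over a single-level
  vocabulary (e.g. only the top level of a functional catalogue), no
  propagation.
* **Correlated growth (`C`).** Pearson correlation of per-condition
  log-ratio profiles $L_{i,t} = \log_2(g_{i,t}/\bar g_i)$, with
  $\bar g_i$ the strain's control mean. The log base cancels in the
  correlation. Pairs with a missing profile are excluded from the `C`
  edge set; zero-variance profiles are reported missing.

The implementation of $n_{ij}$ uses a protein-by-term incidence matrix;
tests verify exact agreement with a brute-force superset scan up to
$N = 200$.

# The homogeneity test

Interacting pairs are systematically more similar than random pairs
(synthetic data reproduce this contrast), so community enrichment against
random protein sets would flatter every community. Instead, each
interacting pair's similarity is standardised against **all interacting
pairs** of the network, $z_{ij} = (S_{ij} - \mu)/\sigma$, and a community
is scored by the mean $z$ over its internal scored edges.

Conventions, each deliberate:

* $\sigma$ is the **population** standard deviation (divide by $n$): the
  scored pair set is the entire population of interacting pairs, not a
  sample from it. The z-set then has mean 0 and s.d. 1 to machine
  precision, so the whole network as one community can never appear
  homogeneous — an exact, tested identity.
* The call is **strictly greater than** 0.3; a community at exactly the
  threshold is not called. The threshold itself is not arbitrary: the
  aggregate z for $n$ pairs is $\sqrt{n}\,\bar z$, so the minimal
  one-sided-0.05 mean is $z_{0.95}/\sqrt{n}$, which is 0.3003 at
  $n = 30$ — communities with 30+ internal pairs clearing 0.3 are
  (approximately) significant, while the mean-based rule stays
  size-even-handed across resolutions. The critical value is computed
  from `qnorm`, never hard-coded. This is intentionally not a formal
  multiple-testing-corrected significance claim.
* Communities with **no scored internal edge** are excluded (`NA`), not
  counted as non-homogeneous: absent data is not negative evidence.
* The size-$\ge 4$ filter applies to *reporting* (`sweep_summary()`,
  ROC evaluation), not to the test: `call_communities()` returns every
  community with a `meets_min_size` flag.

Calibration is tested empirically: with annotations shuffled across
proteins, the per-community mean z distribution centres at zero and at
most ~10% of size-$\ge 4$ communities pass at 0.3, while with perfect
annotation fidelity essentially all recovered planted modules pass.

# Topological metrics and prediction

Fourteen community-level metrics are implemented (mean degree, degree
assortativity, mean clustering coefficient, mean betweenness, closeness,
eigenvector centrality, mean/harmonic-mean geodesic, diameter, cyclomatic
number, density, efficiency, fraction of articulation vertices, largest
adjacency eigenvalue), all computed on the community's **induced
subgraph**: a topological predictor of a community's functional coherence
should reflect its internal wiring, not its embedding. A whole-network
variant of the clustering mean is available behind a flag for sensitivity
checks. Degenerate-case policy: degree-<2 nodes have clustering 0 (kept,
not dropped — this keeps the triangle and star examples well defined);
geodesic means use connected pairs only and diameter is the maximum over
components; single-node communities have missing density/diameter;
assortativity on regular subgraphs is missing; efficiency is the mean
inverse geodesic over connected pairs and hence exactly the reciprocal of
the harmonic-mean geodesic (a tested identity). Eigenvector centrality
uses the package-standard ARPACK routine, with failures mapped to missing
values.

Each metric is scored as a classifier of the homogeneity labels: sweep a
threshold over its values, trace the ROC curve, take the area. Ties get
Mann–Whitney half credit (diagonal segments), so the trapezoidal area
equals the tie-corrected rank statistic — both are computed and
cross-checked, including against an external ROC implementation. AUCs
below 0.5 indicate below-threshold prediction and are reported unflipped.
Per-resolution AUCs are averaged (unweighted) over
$0 \le \log_{10}\lambda \le 3$; the noisy low-resolution end, where only
a handful of communities exist, is excluded, and grid points where only
one class survives are skipped and reported as reduced coverage.

# What the synthetic data emulate — and what they do not

The generators provide every input with known ground truth:

* **Network** (`generate_planted_network()`): a two-level hierarchical
  stochastic block model, 4 coarse × 3 fine × 15 nodes with edge
  probabilities 0.6 (within fine) / 0.15 (within coarse) / 0.01
  (between) by default — strong communities at two well-separated
  scales, with overall mean degree (~14) in the range of dense
  interaction data. Two levels suffice to exercise multi-resolution
  recovery; deeper hierarchies would be a configuration extension, and
  degree-matched (configuration-model) rewiring is out of scope.
* **Annotations** (`generate_annotations()`): a three-level rooted tree
  (root → coarse branch → fine leaf sets, plus 20 background terms under
  the root). Each protein carries its module's leaf set with probability
  `fidelity`, else a single random background term — so infidel proteins
  behave like sparsely annotated ones, keeping unannotated-pair
  semantics exercised. Fidelity 0.9 is the default working point:
  strong but imperfect annotation, as for a well-studied organism.
* **Growth profiles** (`generate_growth_profiles()`): each fine module a
  latent standard-normal response over 418 conditions (the scale of
  published homozygous-deletion growth screens); protein profiles are
  `effect_size × module vector + N(0, noise_sd²)` on the log-ratio
  scale, with an optional unprofiled fraction mirroring lethal
  deletions. "Strong growth signal" in the concordance tests means
  effect size 2 at noise s.d. 0.5 (pairwise within-module correlation
  ≈ 0.9). Profiles are generated directly as log-ratios; the raw-rate
  writer (`control_mean * 2^L`) exercises the read-side transform.
* **Mixed benchmark** (`generate_mixed_benchmark()`): a planted network
  joined to an Erdős–Rényi region of comparable size by a few random
  bridges, with background-only annotations in the random part. This is
  the testbed for topological prediction: it contains both genuinely
  coherent dense communities and incoherent sparse ones, the contrast a
  predictor must exploit. On a *pure* planted benchmark with
  near-perfect annotations almost every community is homogeneous and
  the rare negatives are coincidental dense bridge cliques, so
  clustering-based prediction inverts — a property of that degenerate
  condition, not of the metric.

All randomness flows from a single integer seed per generator call
(scoped with `withr`, so the caller's RNG state is untouched), and
identical seeds give byte-identical serialised outputs. The unprofiled
set is thinned by an exact rounded count rather than per-protein coin
flips, trading binomial jitter for determinism of the profiled-set size.

What passing tests on these conditions do **not** show: real interaction
data have heavy-tailed degrees, correlated experimental error, annotation
bias toward well-studied complexes, and unknown hierarchy depth. The
synthetic benchmarks validate the machinery (energy accounting, limits,
calibration, orderings), not any biological claim about a particular
proteome.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run on 180-node benchmarks
with 0.1-dex resolution grids (41 points), 20–50 seed replicates for
stochastic checks, and exhaustive partition enumeration up to 8 nodes
(4140 partitions); a full sweep takes well under a second, the whole
suite about a minute. The published-protocol grid spacing of 0.01 dex is
available but unnecessary at these network sizes. Energy comparisons use
an absolute slack of 1e-9; the optimiser accepts moves only above a 1e-12
gain to avoid tie-cycling.

Known limitations: unweighted, undirected networks only; no overlapping
communities; greedy optimisation only (no annealing or spectral
refinement); no information-content (Resnik/Lin-style) similarities; no
multiple-testing correction across communities, by design of the
mean-z rule.
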