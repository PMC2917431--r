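# pottsnet

Multi-resolution community detection and functional-homogeneity analysis
for protein–protein interaction networks.

Protein interaction networks have organisation at many scales — complexes
nested inside pathways nested inside broad functional neighbourhoods — so
no single partition tells the whole story. `pottsnet` detects communities
across a continuum of scales by minimising a Potts-model energy

    H = − Σ_{i≠j} ( B_ij − λ k_i k_j / (2W) ) δ(s_i, s_j)

over a logarithmic grid of the resolution parameter λ, where `B` is the
adjacency matrix, `k_i` the degree, `W` the edge count and `s_i` the
community of node `i`. At λ = 1 this is (−2W times) standard
Newman–Girvan modularity; λ → 0 collapses everything into one community,
and once every entry of `J = B − λ·kk'/(2W)` is negative each node sits
alone. Optimisation is a seeded Louvain-style greedy heuristic
(single-node moves plus community aggregation), and a node-overlap
convention keeps community labels consistent as λ changes.

Each community is then tested for **functional homogeneity** with an
interaction-controlled z-test. Interacting pairs are more functionally
similar than random pairs, so a fair test standardises each interacting
pair's similarity against all interacting pairs of the network:

    z_ij = (S_ij − μ) / σ

with μ, σ the mean and (population) s.d. of the similarity `S` over all
scored interacting pairs. A community is called functionally homogeneous
when the mean `z_ij` over its internal edges exceeds 0.3 — the one-sided
0.05 critical mean for 30 or more internal pairs, since
`qnorm(0.95)/sqrt(30) ≈ 0.300`. Three similarity measures are supported:

* `G` — shared-annotation rarity over a term ontology (DAG-propagated):
  `G_ij = 1 − n_ij/N`, where `n_ij` counts proteins whose annotation set
  contains the pair's shared term set;
* `M` — the same rarity measure over a flat top-level vocabulary;
* `C` — Pearson correlation of knock-out growth log-ratio profiles
  across conditions.

Finally, community-level topological metrics (mean clustering
coefficient, geodesic statistics, centralities, density, …) are evaluated
as *predictors* of functional homogeneity via ROC curves, summarised as
the mean AUC over 0 ≤ log₁₀(λ) ≤ 3.

Everything runs against synthetic benchmarks with known ground truth:
two-level planted-community networks, annotations with tunable fidelity,
and growth profiles with tunable effect size — so each stage of the
pipeline is testable without any external download.

## Worked example

```r
library(pottsnet)

gen <- generate_planted_network(seed = 1)   # 4 coarse x 3 fine x 15 nodes
network_summary(gen$network)
#>   n_nodes n_edges n_self_edges mean_degree mean_clustering
#> 1     180    1277            0    14.18889       0.2910064

sw <- potts_sweep(gen$network, log_min = -1, log_max = 3, step = 0.1,
                  seed = 1)
sw
#> Potts resolution sweep: 41 grid points, log10(lambda) in [-1, 3]
#>   180 nodes; communities: 1 (coarsest) to 180 (finest)
#>   warm_start = TRUE, relabeled = TRUE, seed = 1
```

The sweep resolves the two planted scales in order: the 4 coarse modules
appear just above λ = 1 and the 12 fine modules are recovered exactly
(normalised mutual information 1.0) at log₁₀(λ) = 0.6.

Annotations at fidelity 0.9 drive the homogeneity test:

```r
ann <- propagate_annotations(
  generate_annotations(gen$structure, fidelity = 0.9, seed = 2))
ez <- zscore_edges(edge_similarity(gen$network, "G", ann, seed = 1))
calls <- call_communities(sw, gen$network, list(G = ez))
s <- sweep_summary(calls)
s[round(s$log_lambda, 1) %in% c(0.1, 0.6), ]
#>  log_lambda measure n_communities n_proteins n_homogeneous n_proteins_homogeneous
#>         0.1       G             4        180             1                     45
#>         0.6       G            12        180             4                     60
```

At the coarse scale one of the four modules clears the 0.3 threshold; at
the fine-module scale more proteins sit in homogeneous communities —
the number of proteins in homogeneous communities peaks at an
intermediate resolution, not at the coarsest one.

On the mixed benchmark (planted modules joined to a random region),
topological metrics are scored as homogeneity predictors:

```r
mb <- generate_mixed_benchmark(seed = 1)
a <- propagate_annotations(mb$annotations)
sw2 <- potts_sweep(mb$network, -1, 3, 0.1, seed = 1)
calls2 <- call_communities(sw2, mb$network,
  list(G = zscore_edges(edge_similarity(mb$network, "G", a, seed = 1))))
mets <- sweep_metrics(sw2, mb$network,
  c("mean_clustering", "mean_geodesic", "density"), min_size = 4)
metric_ranking(metric_aucs(mets, calls2))
#>           metric  mean_auc  coverage
#>          density 0.8917363 0.6470588
#>  mean_clustering 0.8838949 0.6470588
#>    mean_geodesic 0.1082637 0.6470588
```

Dense, tightly clustered communities predict functional homogeneity
(AUC ≫ 0.5); mean geodesic distance is *negatively* associated
(AUC ≪ 0.5, reported as-is).

The whole pipeline, with per-stage CSV outputs and a manifest, is one
call:

```r
run_pipeline(list(outdir = "demo_run", seed = 1))
```

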