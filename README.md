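# wgcnam — weighted gene co-expression networks with modularity maximization

`wgcnam` builds weighted gene co-expression networks from RNA-seq-derived
expression matrices and detects gene modules by maximizing modularity or
modularity density, replacing dendrogram cutting (and its `minClusterSize` /
`deepSplit` parameters) with an objective-driven community search. It is
aimed at analysts who already have per-contrast differential-expression
tables and a normalized expression matrix, and who want module detection
with few tunable parameters, a permutation test for whether the modular
structure exceeds chance, and honest accounting of unassigned genes.

## The method

Given an *n × m* expression matrix *X* (genes × samples), the pipeline:

1. **Feature selection** — combines per-timepoint DE tables (for a gene
   significant in several contrasts, the row with the lowest FDR is kept)
   and filters to FDR ≤ 10⁻⁵ and fold change ≥ 1.5 (|log₂FC| ≥ 0.59).
2. **Network construction** — Pearson correlation *r·ᵢⱼ* between gene
   profiles; soft-threshold adjacency *aᵢⱼ = |rᵢⱼ|^β* with β chosen as the
   smallest power whose connectivity distribution fits a scale-free topology
   at *R²* ≥ 0.9 (or fixed by the user); hard edge filter keeping pairs with
   |rᵢⱼ| ≥ 0.7. Genes left without any edge are *unassigned* — they are the
   grey-module analogue.
3. **Module detection** — greedy agglomerative maximization of either the
   weighted Newman modularity
   *Q = Σ_c ( W_c^in / W − (S_c / 2W)² )*
   or modularity density *Q_ds* (a density-weighted variant with an explicit
   split penalty that counteracts the resolution limit), refined by
   single-node moves, community splits and Kernighan–Lin chains.
4. **Significance** — the observed maximized *Q* is compared with the
   maximized *Q* of randomly rewired networks that preserve the edge count
   and the multiset of edge weights (default 1000 permutations), summarized
   as a z-score.
5. **Evaluation** — Rand-index comparison between partitions (each
   unassigned gene counted as a cluster by itself) and an FDR-sweep that
   picks the selection cutoff maximizing the median module size.

A synthetic-data module generates planted co-expression modules
(latent-factor construction with controllable within-module correlation ρ)
and negative-binomial counts with condition × timepoint DE effects, so every
stage can be exercised without external data.

## Worked example

```r
library(wgcnam)

# 5 planted modules of 20 genes (rho = 0.95) plus 10 noise genes, 30 samples
sim <- simulate_modular_expression(sizes = rep(20, 5), within_correlation = 0.95,
                                   n_noise_genes = 10, n_samples = 30, seed = 1)
graph <- build_network(sim$expr, beta = 16, min_abs_cor = 0.7)
graph
#> Co-expression graph: 110 nodes, 950 edges (10 isolated)
#>   soft-threshold power beta = 16
#>   edge filter |r| >= 0.7

det <- detect_modules(graph)
det
#> Module detection (density objective)
#>   5 modules, 10 unassigned genes
#>   Q = 0.7983, Qds = 0.3825
rand_index(det$partition, sim$truth)
#> Rand index: 1.0000 (110 items, 5995/5995 agreeing pairs); adjusted: 1.0000

ns <- module_significance(graph, n_permutations = 200, seed = 2)
ns
#> Permutation test (200 permutations, uniform null)
#>   observed Q = 0.7983, null mean = 0.0003, null sd = 0.00109
#>   z-score = 731.95
```

The five planted modules are recovered exactly (Rand index 1), the ten noise
genes end up unassigned (they are isolated after the |r| ≥ 0.7 filter), and
the observed modularity lies hundreds of null standard deviations above the
rewired-network null — a strongly non-random modular structure.

The same run from a shell:

```sh
inst/cli/wgcnam simulate --kind expression --out sim/
inst/cli/wgcnam pipeline sim/expression.tsv sim/de_*.tsv --out run/ --seed 1
```

Subcommands `select-features`, `build-network`, `cluster`, `significance`,
`compare`, `sweep` run individual stages on the previous stage's files.

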