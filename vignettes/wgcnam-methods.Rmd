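---
title: "Module detection in weighted co-expression networks by modularity maximization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module detection in weighted co-expression networks by modularity maximization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgcnam)
```

## The model

A co-expression network treats genes as nodes and correlation of expression
across samples as evidence of shared regulation. Starting from an *n × m*
matrix *X* of *n* genes measured in *m* samples, the pipeline computes the
Pearson correlation *r<sub>ij</sub>* between every pair of gene profiles and
converts it to a weighted, unsigned adjacency

*a<sub>ij</sub> = |r<sub>ij</sub>|<sup>β</sup>*,

the soft-threshold construction of weighted co-expression analysis. Raising
to a power β > 1 suppresses weak correlations smoothly instead of cutting at
an arbitrary value; β is chosen as the smallest integer power for which the
network's connectivity distribution is approximately scale-free. On top of
the soft threshold, a hard edge filter retains only pairs with
|r<sub>ij</sub>| ≥ 0.7, producing a sparse weighted graph. Genes that lose
every potential edge at this step are *unassigned*: the pipeline's only
mechanism for declaring a gene module-less, equivalent in role to the grey
module of dendrogram-based analysis.

Modules are then communities in this graph. Two objectives are available:

* **Weighted Newman modularity.** For a partition into communities *c* with
  internal weight *W<sub>c</sub><sup>in</sup>*, total strength
  *S<sub>c</sub>*, and total edge weight *W*:
  *Q = Σ<sub>c</sub> ( W<sub>c</sub><sup>in</sup>/W − (S<sub>c</sub>/2W)² )*.
  Q compares in-community weight with its expectation under a
  strength-preserving random graph. It is the field's standard quality
  index but suffers from the resolution limit: in large networks, merging
  small, well-formed communities can raise Q even when they are clearly
  distinct.

* **Modularity density** (the default optimization target). With internal
  density *d<sub>c</sub> = 2W<sub>c</sub><sup>in</sup>/(n<sub>c</sub>(n<sub>c</sub>−1))*
  (defined as 0 for singletons, where the denominator vanishes) and pair
  density *d<sub>cc'</sub> = W<sub>cc'</sub>/(n<sub>c</sub>n<sub>c'</sub>)*,
  each community contributes

  (W<sub>c</sub><sup>in</sup>/W)·d<sub>c</sub> −
  ((2W<sub>c</sub><sup>in</sup> + W<sub>c</sub><sup>out</sup>)/(2W)·d<sub>c</sub>)² −
  Σ<sub>c'≠c</sub> (W<sub>cc'</sub>/(2W))·d<sub>cc'</sub>,

  with edge weights in place of edge counts throughout. Weighting by
  density and penalizing splits explicitly removes the resolution-limit
  bias toward over-merging.

Whichever objective drives the search, the standard Q of the final partition
is always reported, since it is the community-quality number readers expect.

## The optimizer

Module detection maximizes the chosen objective with a deterministic greedy
scheme written in C++:

1. **Agglomeration.** Every non-isolated node starts as its own community;
   the community pair whose merge yields the largest positive gain is merged
   repeatedly until no merge helps. For Q, only pairs connected by at least
   one edge are candidates (a zero-weight merge provably lowers Q). For
   modularity density this restriction would be wrong: merging two
   *non-adjacent* communities can strictly raise the objective, because the
   split penalty uses pair densities *W<sub>cc'</sub>/(n<sub>c</sub>n<sub>c'</sub>)*
   and a larger community dilutes them. All pairs are therefore candidates
   under the density objective.
2. **Fine-tuning.** Sweeps of best-improvement single-node moves (to any
   candidate community, or out into a fresh singleton), community split
   proposals (greedily peeling members into a new community and keeping the
   best prefix), and renewed merges, iterated to a local optimum.
3. **Kernighan–Lin refinement.** When no single step helps, a chain of
   relocations is explored in which each step takes the best available move
   even at a temporary loss, each node moving at most once; the
   best-scoring prefix of the chain is kept if it improves the objective.
   This escapes traps where a better partition is reachable only through a
   coordinated rearrangement.

All candidate scans run in a fixed order and accept only strictly larger
gains, so ties resolve to the smallest label pair and a single run is fully
deterministic. Optional restarts (default: one run) randomize the greedy
merge choice among all positive-gain candidates under the caller's seed and
keep the best local optimum; on small graphs a handful of restarts
reliably reaches the global optimum found by exhaustive enumeration, which
is how the optimizer is validated in the test suite. Convergence uses a
gain tolerance of 10⁻¹².

Isolated nodes never enter the optimization; they are returned as
unassigned. A configurable `min_module_size` (default 1, i.e. inactive) can
additionally demote tiny communities to unassigned. Final modules are
relabelled in decreasing size order.

One property worth knowing: Q is scale-free in the edge weights, so
multiplying all weights by a constant changes nothing. Modularity density
is *not* — its terms mix linear and quadratic functions of the weights — so
the optimal partition under Qds can in principle depend on the overall
weight scale. The soft-threshold adjacency fixes the scale to (0, 1], which
keeps runs comparable.

## Significance of the modular structure

Any community-detection method returns *some* partition; the permutation
test asks whether the observed modularity exceeds what optimization alone
extracts from an equally dense, equally weighted but unstructured network.
Each permutation redraws the same number of edges uniformly at random over
distinct node pairs (no self-loops, no duplicates) and reassigns the
observed weight multiset to them in shuffled order; the permuted network is
then re-clustered from scratch and its maximized Q recorded. The summary is
*z = (Q<sub>obs</sub> − mean Q<sub>null</sub>)/sd(Q<sub>null</sub>)*.

Two modelling notes. First, the null statistic is the *maximized* Q of each
permuted network, not the observed partition rescored on it — "modularity of
a network" means its optimized value, and this is the conservative choice
(the null mean is higher). Second, uniform rewiring does not preserve the
degree distribution, so the null networks are not scale-free even when the
observed network is; a degree-preserving alternative based on double-edge
swaps is available as `null_model = "degree"` for users who want the
stricter null. Since each permutation re-runs the optimizer, the default
1000 permutations is the main cost of a full run; the desk-scale test suite
and the acceptance script use 200, which already pins the null mean and
standard deviation well (the Monte-Carlo error of the null mean shrinks as
1/√B over permutations B).

## Comparing partitions

Partitions from different methods are compared with the Rand index, the
fraction of gene pairs on which two partitions agree (together in both or
apart in both). Unassigned genes need care: they are *not* similar to each
other, so before pair counting every unassigned gene is converted into a
cluster by itself in its partition. Treating the unassigned set as one
shared cluster would reward two methods for jointly failing on the same
genes. The adjusted Rand index is reported alongside as a convenience, but
the headline number is the plain RI under the singleton convention.

## Choosing the selection cutoff

Feature selection keeps genes at FDR ≤ 10⁻⁵ and fold change ≥ 1.5 by
default. The FDR bound can be varied; `fdr_sweep()` re-runs
selection → network → clustering over a cutoff grid and records gene count,
module count and the median module size at each value, selecting the cutoff
that maximizes the median module size — very small modules are hard to
interpret, so the sweep favors the strictest list that still yields
substantial modules. The median is taken over assigned modules only;
unassigned singletons are not clusters in the pipeline's own output, though
the module count is recorded too so either summary can be read off. Cutoffs
admitting fewer than three genes (or no edges) are flagged degenerate rather
than failing the sweep.

## What the synthetic generator emulates

`simulate_modular_expression()` plants each module around one latent factor
(the module's eigengene): a standard-normal profile *f* across samples with
members *x<sub>ij</sub> = √ρ·f<sub>j</sub> + √(1−ρ)·ε<sub>ij</sub>*, giving
expected within-module correlation exactly ρ. This is the simplest
construction matching the working model of a module — genes correlated with
one underlying profile — with a single knob for module tightness. Noise
genes are independent normals and should end up unassigned. Defaults for
the end-to-end checks are five modules of 20 genes, ρ = 0.95, 10 noise
genes and 30 samples — module tightness high enough that the |r| ≥ 0.7
filter at 30 samples retains within-module edges with high probability, and
a sample count matching a two-group, five-timepoint, three-replicate design.

`simulate_counts()` emulates the upstream count data: log-normal baseline
means, log-normal library-size factors, negative-binomial sampling at
constant dispersion (default 0.1), and a planted DE fraction shifted by a
fixed log₂ fold change in the treated group at every timepoint.
`de_test_lognormal()` turns such counts into DE tables using a plain Wald
test on log-transformed normalized counts with BH correction per timepoint.
It is deliberately simple and is *not* equivalent to a negative-binomial
GLM analysis (no dispersion shrinkage, no quasi-likelihood test); real
analyses should feed externally produced DE tables into the pipeline.

What passing tests on these simulations show — and what they do not: the
latent-factor model produces clean block correlation structure, so planted
recovery demonstrates the correctness of the machinery (thresholding,
optimization, unassigned handling), not robustness to the overlapping
modules, hub genes, heavy-tailed counts and batch effects of real RNA-seq
data. In particular, the planted block structure is *not* scale-free, so
the automatic β selection correctly reports the target R² as unmet on such
toys and end-to-end checks fix β instead (β = 16, a value typical for
unsigned networks on real data).

## Numerical and design choices

* **Unsigned network.** The edge filter applies to |r|, consistent with the
  power function on |r|; strongly anti-correlated genes are connected. A
  signed variant would simply skip the absolute value; it is not currently
  exposed because every downstream quantity (adjacency, thresholding)
  consumes |r|.
* **Diagonal.** The adjacency diagonal is 0: no self-loops, and a gene's
  connectivity *k<sub>i</sub> = Σ<sub>j</sub> a<sub>ij</sub>* excludes
  itself.
* **Scale-free fit.** Connectivities are binned into 10 equal-width bins
  (configurable); log₁₀ frequency is regressed on log₁₀ mean connectivity
  over non-empty bins, and R² is computed directly from sums of squares so
  an exact power law yields exactly 1. The fit errors out when all
  connectivities are equal and flags (rather than fails) when no candidate
  power reaches the target R², returning the best power found.
* **Combination ties.** When a gene attains its minimum FDR in two
  comparisons, the row with the larger |log₂FC| wins, then the
  lexicographically smaller comparison label — determinism over an
  arbitrary but documented preference.
* **Edge weights for clustering** are the soft-threshold adjacencies, not
  the raw correlations: the clustered object is the weighted, thresholded
  adjacency matrix.
* **Degenerate inputs.** Constant expression rows are rejected by name
  before correlation; empty or edgeless graphs are errors for detection; a
  degenerate permutation null (all permuted Q identical) yields `z = NA`
  with a warning rather than an infinity.
* **Problem sizes.** The test suite validates scoring against brute-force
  oracles on all partitions of graphs up to 8 nodes, optimizer optimality
  against exhaustive enumeration up to 7 nodes, and the end-to-end run on
  110-gene planted networks with 200-permutation nulls — sizes chosen so
  the full suite runs in well under a minute of optimizer time while still
  exercising every code path at non-trivial scale.

## Known limitations

* The optimizer is a polished local search, not an exact solver; global
  optimality is verified only at enumeration scale, and on large networks
  different restart seeds can yield slightly different partitions (the
  reported objective orders them).
* The uniform permutation null ignores degree structure; use the
  double-edge-swap null when degree preservation matters.
* Modularity density's weight-scale dependence means Qds values are
  comparable only between networks built with the same β.
* The pipeline consumes DE tables; it does not estimate dispersions or fit
  count GLMs, and the included count-data test is a stand-in for synthetic
  runs only.
* Dendrogram-based module detection and its partitions are consumed from
  files for comparison, never recomputed.
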