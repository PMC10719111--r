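# brainatlas

Tested R implementations of the computational procedures used to build
whole-mouse-brain single-nucleus RNA-seq + Slide-seq cell-type atlases, for
computational biologists who want to apply, audit or extend the individual
steps. Every stage is exercised end to end on synthetic data with known
ground truth, so no data download is required to validate any claim the
package makes.

## What it implements

**Recursive cluster discovery.** Each round selects variable genes by their
deficit of detection under a binomial model — for a gene with relative bulk
expression *p* in a cell of depth *n*, homogeneous expression predicts
detection probability 1 − e^(−np); genes observed ≥ 5 points below
expectation are selected — then builds a cosine kNN (k = 50) / Jaccard SNN
graph on √counts, sweeps Leiden resolutions under the Constant Potts Model
until ≥ 2 clusters with size ratio ≤ 20 appear (discarding clusters below
√N), and recurses. Clusters survive only if every sibling pair is separated
by ≥ 3 discrete markers in each direction (detected in < 10% of the low
side, ≥ 20 points higher on the high side, Mann–Whitney significant).

**Bead decomposition with a confidence score.** Beads (≥ 150 UMIs total,
≥ 20 in a region's tailored 5,000-gene list) are decomposed against
per-region references (types with ≥ 100 cells total, ≥ 50 in-region) under a
Poisson mixture likelihood with weights *w* ≥ 0, Σw ≤ 1. Candidate types
come from ridge-penalized full fits (strengths 0.01 and 0.001) plus singlet
fits; all pairs touching the top-10 candidates are scored, pairs within 30
log-likelihood units of the best form the well-fitting set, and a type's
confidence is its occurrence frequency among those pairs (maximum 0.5;
"confident" above 0.3).

**Minimal marker panels.** The smallest gene combination uniquely defining a
type (all selected genes "on" in the target, each other type "off" for at
least one) is found by exact branch-and-bound set cover, with gene-family
enrichment of the chosen markers.

**Neurochemistry.** Rule-based neurotransmitter assignment at a nonzero
threshold of 0.35 (nine identities, e.g. GABA = (Gad1|Gad2) & Slc32a1),
neuropeptide/receptor thresholds with the strict override for Oxt, Avp,
Pmch and Agrp, and regional inhibitory fractions #I/(#I+#E) with exact
binomial intervals.

**Regional diversity.** Cell types needed to cover 95% of a region's mapped
beads, weighted-Jaccard region similarity, and dendrogram-neighbourhood
extraction (cap 100 types, 60% non-neuronal stopping rule).

**Pseudocells and activity-regulated genes.** Within-type aggregation at
size s = min(200, max(20, n/50)); log2-CPM → quantile → z normalization;
ARG candidates per cell group (Fos correlation ≥ 0.3, ≥ 99.5% quantile of
the gene's correlations, Holm p < 0.05), bipartite gene-region network
(prune e = r + 1 < 1.3, core degree > 18), ward.D2 ARG clusters, Fisher
overlap tests.

**Sampling saturation.** The multinomial probability that each of k rare
types (frequency p) is sampled ≥ c times among n cells, via the
independent-Poisson approximation [P(Pois(np) ≥ c)]^k with exact binomial
(k = 1) and Monte-Carlo cross-check modes, plus inversion for the smallest
sufficient n.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on synthetic
data and write their tables under `results/`. Running them in order prints,
among other things:

```
== analysis/03_cluster.R
cluster_tree: 8 leaves over 5000 cells; 0 discarded
leaves: 8 | ARI vs truth: 0.986 | discarded: 0

== analysis/04_map.R
bead_mapping: 2000 beads, 2000 eligible
beads with a confident call: 1976 of 2000 eligible

== analysis/05_markers.R
median cover size: 1
planted-marker family odds ratio: Inf  p: 1.33e-08

== analysis/09_saturation.R
required cells per rare type: 81
rare-type frequency: 0.0024 %
saturation at the full depth (4,388,420): 0.889
Monte-Carlo cross-check: 0.89 +/- 0.0031
```

Reading: recursive clustering recovers exactly the 8 planted types
(adjusted Rand index 0.986 against the ground-truth labels); 1,976 of 2,000
simulated beads get a confident cell-type call; each discovered cluster is
uniquely identified by a single planted marker gene (so the minimal covers
are heavily enriched for the planted-marker family); and at the atlas's
published scale — 19 rare types of 101 cells among 4.21 million mapped
nuclei, requiring 81 cells each — the sampling-saturation model puts the
success probability at 0.889 for the full 4.39-million-nucleus dataset,
with the exact multinomial Monte Carlo agreeing within its standard error.

A minimal interactive session:

```r
library(brainatlas)
truth <- build_ground_truth(n_types = 8, n_genes = 200, n_regions = 2, seed = 1)
cells <- simulate_cells(truth, n_cells = 5000, depth_median = 5000, seed = 2)
tree  <- iterative_cluster(cells, seed = 7)
tree
#> cluster_tree: 8 leaves over 5000 cells; 0 discarded
```

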