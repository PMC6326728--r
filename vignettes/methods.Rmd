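---
title: "Localizing an ISR signature across CNS cell types: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing an ISR signature across CNS cell types: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`isrmap` asks a localization question: given droplet single-cell RNA-seq of
a tissue carrying a chronic integrated stress response (ISR), which cell
types express an ISR gene signature at baseline, and in which types does a
mutant genotype elevate it further? This vignette documents the models
behind each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices a maintainer would want spelled out.

## Droplet barcode filtering

Per-barcode UMI totals from a droplet run are a mixture: a low mode of
ambient-RNA ("empty") droplets and a high mode of cell-containing droplets.
`build_umi_histogram()` bins log10 totals (bin width 0.05 log10 units,
centered moving-average smoothing over 3 bins) and `find_umi_threshold()`
returns the center of the first bin that is a strict local minimum of the
smoothed counts at or above a floor of 2 (i.e. 100 UMIs). Barcodes at or
above the threshold are retained (`>=`, a deterministic boundary
convention). The bin width and window are not dictated by the procedure the
floor comes from; 0.05 is fine enough to localize the valley between modes
while the 3-bin smoother suppresses single-bin Poisson minima in the tail.
A histogram with no qualifying minimum raises a typed condition
(`isrmap_no_threshold`) rather than guessing; the caller may lower the
floor explicitly.

## Normalization, variable genes, PCA

Counts are depth-normalized to 10^4 per cell and transformed with
`log1p`; zeros stay zero, so sparsity is preserved, and a cell's profile is
invariant to its sequencing depth. Variable genes are selected by
dispersion (variance/mean of normalized expression), z-scored within 20
equal-occupancy bins of the gene mean, keeping genes with z >= 1 and mean
in [0.0125, 3]. PCA retains the 50 leading components after per-gene
centering and unit scaling (zero-variance genes are dropped with a
warning).

The PCA is always an exact eigendecomposition of whichever Gram matrix
(gene x gene or cell x cell) is smaller. At the problem sizes this package
targets (up to ~16,000 cells by ~2,000 variable genes) the exact
decomposition takes seconds, so no randomized solver is used at any size;
this keeps the embedding bit-reproducible without seed bookkeeping. A
deterministic sign convention (the largest-magnitude coordinate of each
component is nonnegative) fixes the remaining SVD ambiguity.

## SNN graph and Louvain clustering

The neighbor set of a cell is itself plus its K = min(750, #cells - 1)
nearest cells by Euclidean distance in PC space, ties broken toward the
lower cell index; including the cell itself makes the two-cell case well
defined. For every pair sharing a neighbor, the edge weight is the Jaccard
index of the two neighbor sets; edges below 1/15 are pruned. The cutoff is
applied to the Jaccard *similarity*: reading it as a distance cutoff would
discard precisely the strong edges. Intersections are computed blockwise
(sparse pattern-matrix products, ~2x10^7 accumulator entries per block)
with immediate pruning, so the dense intersection matrix is never held.

Louvain community detection maximizes the resolution-scaled modularity

$$Q(r) = \sum_c \left[\frac{W_{in}(c)}{W} - r\left(\frac{S_c}{2W}\right)^2\right]$$

by local moving and graph aggregation repeated to a fixed point. The kernel
is compiled (Rcpp): a 48-point resolution scan over a ~13-million-edge
graph finishes in ~2.5 minutes where an interpreted or generic
implementation takes tens of minutes. Node sweep order is shuffled with R's
RNG, so `set.seed()` upstream reproduces partitions exactly. On graphs of
up to 8 nodes the implementation attains the exhaustively enumerated
modularity optimum (best of 10 seeds) in the test suite, and it is
cross-checked against `igraph::cluster_louvain()`.

### The resolution search and its metric

The resolution parameter is scanned over 0.05 to 1.225 in steps of 0.025
(48 points; the endpoints are the procedure's, the step is this package's
choice). Each partition is scored by a mean unifiability/isolability
metric: per community, *unifiability* is the weighted internal edge density
W_in(c) / (|c|(|c|-1)/2) (1 for singletons; Jaccard weights bound it by 1)
and *isolability* is 1 - W_cut(c)/(W_in(c)+W_cut(c)) (1 for an isolated
community); the metric is the mean over communities of their average, and
the smallest resolution attaining the maximum wins. The metric is bounded
in [0, 1], penalizes over-merging through density and over-splitting
through the cut fraction, and is maximized exactly by partitions into
disconnected dense modules. It is one operationalization of a quantity the
underlying procedure names but does not define; it is isolated behind
`partition_metric()` so it can be swapped.

### Iterative sub-clustering

Each cluster is then re-analyzed alone — variable genes, PCA, SNN graph and
resolution search are re-run on its cells — and a proposed split is
accepted when (i) it has at least two communities of at least `min_cells`
(default 10) cells and (ii) it does not lower the metric contribution
computed on the SNN graph built from the cluster's own cells. Convergence
is "no cluster can be broken down further"; leaves are processed in
ascending label order, and hierarchical labels extend with dot suffixes
("3.1"). The acceptance comparison deliberately uses the sub-graph the
split was found in: measured on the parent graph, children always pay the
cut between themselves, which vetoes legitimate splits of merged
super-types; measured on their own graph, a homogeneous cluster presents a
near-complete weight-1 graph whose single-community metric is 1, so it
never splits.

### Why the defaults assume concatenated samples

K = 750 interacts with cluster size: when a type holds fewer than K cells,
every neighbor set must spill into other types, the spills concentrate on
the same low-noise cells, and cross-type Jaccard weights stay far above
1/15 — the graph densifies and no metric can isolate the types. The
constants are therefore meaningful in the regime where clusters exceed K,
i.e. several concatenated samples. The package's end-to-end recovery runs
use four concatenated simulated samples (10 types x 1,600 cells after QC);
a single 4,000-cell sample is used where only the barcode filter is
exercised. With that design the pipeline recovers the planted 10 types at
adjusted Rand index 1.0.

## The bimodal likelihood-ratio test

For each gene and cell group, normalized expression is modeled as exactly
zero with probability 1 - pi and Gaussian(mu, sigma) otherwise; pi is the
detection fraction and mu, sigma the moments of the positive values, with
sigma floored at 10^-3 (the MLE is degenerate below two positive values).
The test statistic is 2(l_A + l_B - l_pooled), chi-square with 3 degrees of
freedom; when either group has fewer than two positive values the Gaussian
component is dropped from both models and the statistic reduces to a 1-df
likelihood ratio on detection alone. Whether the original test shared sigma
across groups is not documented; this implementation fits sigma per group.
Under its own null the type-I error at alpha = 0.05 is calibrated within
[0.03, 0.07] (2,000 null genes, n = 50/50, in the test suite).

Markers of a cluster are genes tested against all other cells (detection
prefilter 0.1 in either group), adjusted by Bonferroni (the era's default;
Benjamini-Hochberg available), flagged at adjusted p < 0.05 with the higher
mean in the cluster. Ranked lists for enrichment use the signed statistic
direction x (-log10 p), computed from log-scale p-values so extreme
statistics do not underflow, with ties broken by LRT statistic and then
gene id.

## Cell-type probability scoring

For a cluster and a candidate type, every marker of the type expressed in
the cluster contributes (mean normalized expression over *all* cluster
cells) x (fraction of cells detecting it); the sum is divided by the type's
total panel size — expressed or not — to remove ascertainment bias from
unequal panel sizes, and the per-type scores are normalized to sum to one.
A cluster is assigned the type whose probability strictly exceeds 0.5,
otherwise it is `UNASSIGNED`. "Expressed in the cluster" means detected in
at least one cell (a configurable minimum detection fraction is provided,
default 0). Ties at exactly 0.5 therefore remain unassigned, and scoring is
scale-equivariant: rescaling expression rescales raw scores but leaves
probabilities and assignments unchanged.

## Preranked GSEA

The enrichment score is the signed maximal deviation of the weighted
Kolmogorov-Smirnov running sum: walking the ranked list, genes in the set
increment by |stat|^p / sum_set |stat|^p (p = 1 by default; uniform 1/k
when all set statistics are zero) and all others decrement by 1/(N - k). An
exact tie between the positive and negative extremes resolves to the
positive one. The null distribution per set is the ES of `n_perm` random
gene sets of the same size drawn from the ranked universe — a gene
permutation; sample permutation is not available from a ranked list.
Nominal p is the one-sided tail frequency among same-sign null scores with
a +1 pseudo-count, NES divides by the mean magnitude of same-sign null
scores, and q is Benjamini-Hochberg across all (contrast, set) results of a
family. Null scores are evaluated only at hit positions (the running sum is
linear between hits), which is algebraically identical to the full sum and
keeps 10^3-10^4 permutations cheap; the equivalence is asserted in tests.

The two contrast families mirror the study design: *basal* contrasts each
cluster's wild-type cells against all other wild-type cells (where does the
signature live at baseline), and *genotype* contrasts mutant against
wild-type cells within each cluster (which types respond to the mutation).
Q-values are computed within each family; the multiple-testing family
behind per-cluster q-values is otherwise unspecified in the source
procedure. In the basal family, clusters other than the signature-bearing
one typically show significant *negative* enrichment — the elevated type
sits in their reference set — so "carrying the signature" means q < 0.05
with ES > 0.

## Bulk eigengene decomposition

A genes x samples matrix (TPM-like) is transformed with ln(x + 1),
gene-centered, and decomposed exactly as X = U S V'. The right singular
vectors are the eigengenes (canonical patterns across samples); U holds the
per-gene loadings. Centering is a deliberate choice (without it the first
component is mean expression, not a sample contrast); both the transform
and centering are flags. Components carry the sign convention above.
Per-component gene classes use the threshold 2 x mean(|loading|): genes
above +threshold form the up class, below -threshold the down class. On the
default bulk simulation (473 up / 600 down genes planted at fold 4, 3
samples per group) the first eigengene separates the genotypes (silhouette
~1) and the classes recover the planted sets with precision and recall
above 0.9.

## The synthetic-data generator

`simulate_droplets()` draws per-gene baseline rates from lognormal(0, 1);
marker and signature genes are re-drawn from lognormal(1, 0.8), the
moderately-to-highly expressed range where curated marker panels live. Each
type's expression program elevates its own markers by `marker_fold`
(default 4) and suppresses other types' markers to `marker_exclusivity`
(default 0.1) of baseline — real cell-type markers are near-exclusive, and
without exclusivity a probability-normalized score over 10 candidate types
is mathematically bounded below 0.5, so the strict assignment rule could
never fire. The 95-gene signature is multiplied by `basal_signature_fold`
(default 3) in the astrocyte-like type(s) and further by
`genotype_signature_fold` (default 2) in mutant cells of the designated
responsive types. Per-barcode totals are log10-normal (cells: mean 3.5, sd
0.2; empties: mean 1.5, sd 0.3 — modes separated as in a clean 10x run);
gene counts given a total are multinomial from the normalized program,
which preserves the UMI-total structure the barcode filter exploits.
Empty droplets draw from the cell-number-weighted average program
(ambient RNA). Defaults describe one sample: 10 types x 400 cells (the
expected recovery of 4,000 cells) with 20,000 empties.

`simulate_bulk()` plants 473 up- and 600 down-regulated genes at fold 4
(defaults) on lognormal baselines with lognormal sample noise (sd 0.2 on
the natural-log scale), then rescales columns to 10^6 (TPM convention).

What the generator does *not* emulate — and hence what green tests do not
certify about real data: doublets, batch and sample effects, ambient-RNA
contamination inside real cells, mitochondrial content, gene-gene
correlation beyond the planted programs, overdispersion beyond multinomial
sampling, and continuous or intermediate cell states. The generator is an
idealization whose role is parameter recovery: every planted quantity is
returned as ground truth so the pipeline can be scored for recovering it.

## Problem sizes used by the test suite and acceptance script

Oracle-equivalence and calibration checks run at small sizes (<= 100 cells
for brute-force graph comparisons; exhaustive partition enumeration at <= 8
nodes; 2,000-replicate nulls). End-to-end recovery runs once at the
four-sample scale (16,000 cells, ~9 minutes) and evaluates the per-seed
scoring and enrichment properties (assignment accuracy over 10 seeds,
genotype-family flags over 20 seeds) on fresh one-sample simulations scored
against the planted partition — the clustering stack's own recovery having
been established by the full run. These sizes are the package's choices for
a reproducible desk-scale analysis.

## Known limitations

* The unifiability/isolability metric and the sub-cluster acceptance rule
  are explicit substitutes for an undocumented original; both are isolated
  behind single functions.
* The bimodal LRT treats cells as independent replicates; no pseudobulk
  aggregation or covariate adjustment is offered.
* Gene-permutation GSEA understates the null variance of strongly
  co-expressed sets (cell-level exchangeability is not modeled); the
  genotype family is therefore sensitive to any covariate that correlates
  with the split inside a cluster.
* The barcode filter assumes a bimodal UMI histogram; heavily degraded
  samples without a clear valley raise `isrmap_no_threshold` by design.
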