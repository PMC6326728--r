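# isrmap

Chronic activation of the integrated stress response (ISR) — the
translational program downstream of eIF2α phosphorylation and reduced
eIF2B activity — underlies Vanishing White Matter disease and related
leukodystrophies. A central question for such disorders is *where* the
response lives: is an ISR gene signature elevated uniformly across CNS cell
types, or concentrated in a susceptible subpopulation such as astrocytes?

`isrmap` implements the transcriptomic inference machinery needed to answer
that question from droplet single-cell RNA-seq and bulk RNA-seq, as a set
of composable R functions plus a one-call pipeline:

* **Droplet QC** — cell-containing barcodes are separated from ambient
  (empty) droplets by the first local minimum above 2 in the histogram of
  log10 per-barcode UMI totals.
* **Embedding** — depth normalization (counts per 10⁴, `log1p`), variable
  gene selection by binned dispersion z-score, exact PCA retaining the 50
  components of highest variance.
* **Clustering** — a shared-nearest-neighbor (SNN) graph with
  K = min(750, #cells − 1) nearest neighbors, edge weights equal to the
  Jaccard index of neighbor sets, pruned below 1/15; Louvain community
  detection (compiled local-moving + aggregation) maximizing the
  resolution-scaled modularity
  Q(r) = Σ_c [W_in(c)/W − r·(S_c/2W)²], with the resolution selected over
  the 0.05–1.225 grid by a mean unifiability/isolability partition metric;
  clusters are then re-analyzed individually and split until no cluster can
  be broken down further.
* **Differential expression** — a bimodal likelihood-ratio test: per group,
  a gene's normalized expression is exactly zero with probability 1 − π and
  Gaussian otherwise; separate-versus-pooled fits give a 3-df LRT (1 df on
  detection alone for degenerate groups).
* **Cell-type assignment** — for each cluster and candidate type, each
  expressed marker contributes (mean expression over all cluster cells) ×
  (fraction of cells detecting it); the per-type sums, divided by panel
  size, are normalized to probabilities and a type is assigned when its
  probability exceeds 0.5.
* **Signature enrichment** — preranked GSEA (weighted Kolmogorov–Smirnov
  running sum) against ranked lists from two contrast families: each
  cluster's wild-type cells versus all other wild-type cells (basal
  localization), and mutant versus wild-type cells within each cluster
  (genotype response); nominal p from a gene-permutation null,
  Benjamini–Hochberg q across clusters within a family.
* **Bulk eigengenes** — SVD of a genes × samples matrix (`ln(x+1)`,
  gene-centered); the right singular vectors ("eigengenes") capture
  expression patterns across samples, and gene classes are extracted per
  component with the threshold |loading| > 2 × mean(|loading|).
* **Synthetic data** — a generator that emulates the assumed study
  structure (transcriptionally distinct types with near-exclusive markers,
  an astrocyte-like type with elevated basal signature, two genotypes with
  mutant-specific signature elevation in designated types, empty droplets,
  and bulk matrices with planted up/down gene classes) together with full
  ground truth, so every stage can be tested for parameter recovery.

## Worked example

```r
library(isrmap)

# simulate a small droplet experiment: 4 cell types, basal ISR elevation in
# type 1, mutant-specific elevation in types 1 and 2
cfg <- cell_sim_config(n_cell_types = 4, cells_per_type = 150, n_genes = 2000,
                       markers_per_type = 40, n_empty_droplets = 3000, seed = 7)
sim <- simulate_droplets(cfg)

# barcode filter: first local minimum of the log10-UMI histogram above 2
thr <- find_umi_threshold(build_umi_histogram(sim$counts))
counts <- filter_barcodes(sim$counts, thr)

# embed and cluster (reduced K for the small example)
norm <- normalize_counts(counts)
emb  <- compute_pca(norm, select_variable_genes(norm), n_pcs = 30)
snn  <- build_snn_jaccard(build_knn(emb, K_cap = 100))
scan <- resolution_search(snn, seed = 1)
clusters <- iterative_subcluster(norm, scan, snn,
                                 pipeline_config(k_cap = 100, n_pcs = 30))

celltype_calls(assign_all(norm, clusters, sim$marker_ref))
truth <- sim$truth[match(colnames(norm), sim$truth$barcode), ]
cluster_signature_analysis(norm, clusters,
                           setNames(truth$genotype, truth$barcode),
                           sim$signature, n_perm = 1000, seed = 1)
```

The filter threshold lands at 2.725 log10(UMI), keeping 600 of 3600
barcodes (exactly the simulated cells). The resolution search selects
r = 0.05 and four clusters, each assigned its generating type with
probability 0.89–0.93:

```
  cluster assignment top_probability
1       1     type03       0.8854884
2       2     type02       0.8908186
3       3     type01       0.9252935
4       4     type04       0.8953060
```

The enrichment table localizes the signature. In the basal family only
cluster 3 — the astrocyte-like `type01` — is positively enriched
(ES = +0.98, q = 0.004; the other clusters show the mirror-image depletion
because the elevated type sits in their reference set). In the genotype
family exactly clusters 2 and 3 (`type02`, `type01` — the types with a
planted mutant response) are flagged:

```
    family cluster     ES    NES p_value q_value
1    basal       1 -0.912 -1.745 0.00366 0.00417
2    basal       2 -0.904 -1.748 0.00341 0.00417
3    basal       3  0.979  1.653 0.00106 0.00417
4    basal       4 -0.890 -1.627 0.00417 0.00417
5 genotype       1 -0.279 -1.028 0.38502 0.51336
6 genotype       2  0.987  2.372 0.00116 0.00238
7 genotype       3  0.992  2.342 0.00119 0.00238
8 genotype       4 -0.225 -0.845 0.80597 0.80597
```

`run_pipeline()` chains the same stages (QC → embed → cluster → markers →
cell type → enrichment) from a 10x-style matrix directory to a directory of
TSV/JSON outputs, driven by a `pipeline_config()` that can be serialized to
YAML.

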