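# myeloregulon

Scoring a myeloid-cell transcription-factor regulon and using it to
stratify immune-checkpoint-inhibitor (ICI) response, from single-cell and
bulk RNA-seq.

Most cancer patients do not respond to checkpoint blockade, and bulk
transcriptomics averages away the cell populations that matter. This
package implements, as tested and reusable R functions, the downstream
analysis arc for one regulon with that discriminative power: **PPARG and
its 23 target genes**, a monocyte/macrophage-specific program whose
per-cell activity and cell-population share are higher in responders. It
is written for computational biologists who want to score the regulon on
their own single-cell or bulk cohorts, or to study the component methods
with full ground-truth control.

## What it computes

* **Single-cell QC** — the four exclusion rules (< 500 expressed genes,
  > 20% mitochondrial UMIs, > 50% ribosomal UMIs, housekeeping UMI sum
  ACTB+GAPDH+MALAT1 < 1) plus a simulation-based doublet score
  (expected rate 0.025).
* **Normalization & clustering** — `log2(1 + count/total * 1e4)`, PCA (20
  PCs), shared-nearest-neighbour Louvain clustering (resolution 0.6),
  Wilcoxon markers (`min.pct = 0.25`), marker-signature annotation, and
  per-sample lineage fractions with the < 10-cell filter.
* **Regulon activity (AUCell-style)** — for each cell, genes ranked by
  decreasing expression; the score is the normalized area under the
  gene-set recovery curve restricted to the top 5% of ranks:

  `score(cell, S) = [ Σ_{k=1..T} |S ∩ top-k| ] / max over T = ⌊0.05·G⌋`

  with binarization (2-component Gaussian mixture / Otsu / fixed) and the
  regulon specificity score `RSS = 1 − √JSD(p_regulon, q_type)`.
* **Regulon modules (CSI)** — `CSI(A,B)` = fraction of other regulons whose
  Pearson correlations with both A and B fall below `PCC(A,B)`;
  hierarchical clustering of the CSI matrix into modules, module activity
  per cell type, and the CSI > 0.7 association network.
* **Myeloid gating & reference mapping** — CD14+/FCER1A− rank-based gating;
  a frozen atlas (scaling, PC loadings, 14 k-means clusters ordered by
  size, per-cluster median PPARG activity; clusters with median > 0.50 are
  response-associated); kNN label transfer of query cells and the headline
  report: the fraction of a sample's myeloid cells in response-associated
  clusters.
* **Bulk GSVA** — the full gene set variation analysis statistic
  (kernel-smoothed cross-sample expression CDFs, symmetrized ranks,
  weighted Kolmogorov–Smirnov walk), one-sided group tests with BH FDR.
* **Survival** — median split of the score, Kaplan–Meier curves and the
  log-rank test; Spearman correlation against covariates.
* **Synthetic data** — a generator planting all of the above structure
  (cell types, the active regulon program, responder enrichment, doublets,
  QC gene classes, pseudo-bulk, linked survival) with per-cell ground
  truth.

## Worked example

```r
library(myeloregulon)

cfg   <- synthetic_config(seed = 101)        # study-condition defaults
cells <- simulate_cells(cfg)                 # 2000 genes x 1600 cells
qc    <- qc_filter(cells)
nm    <- normalize_log(qc$filtered)

# gate myeloid cells and build the reference atlas
gate  <- gate_myeloid(nm)
myel  <- normalized_matrix(nm$values[, match(gate$cell_ids, nm$cell_ids)],
                           nm$transform_tag)
atlas <- build_reference(myel, pparg_regulon(), n_clusters = 14, seed = 107)

# score a held-out query per response group
query <- simulate_cells(synthetic_config(seed = 900))
resp  <- subset_cells(query, query$cell_meta$response == "responder")
pparg_report(resp, atlas)
```

```
ResponseReport: 800 cells -> 800 post-QC -> 141 myeloid
  fraction in response-associated clusters: 0.660
  regulon activity median 0.549 (IQR 0.420)
```

The same report on the nonresponder half gives a fraction of 0.070 and a
median activity of 0.133: the responder sample's myeloid compartment is
dominated by regulon-active cells mapped into the high-PPARG atlas
clusters, the nonresponder's is not — the direction the score is designed
to detect. The numbered scripts under `analysis/` walk the full arc
(simulation → QC/clustering/fractions → activity/modules/RSS → atlas
mapping → bulk GSVA/survival) and write their tables under `results/`.

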