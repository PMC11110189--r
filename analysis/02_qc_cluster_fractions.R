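#!/usr/bin/env Rscript
# QC, doublet scoring, clustering, annotation, and the myeloid-fraction
# comparison on the simulated cohort from 01_simulate_cohorts.R.

suppressPackageStartupMessages(library(myeloregulon))
dir.create("results", showWarnings = FALSE)

cells <- read_cell_matrix("results/data/cohort.mtx",
                          "results/data/cohort.genes.txt",
                          "results/data/cohort.cells.txt",
                          "results/data/cohort.meta.tsv")

qc <- qc_filter(cells)
cat(sprintf("QC: %d of %d cells pass the four exclusion rules\n",
            sum(qc$report$overall_pass), nrow(qc$report)))

ds <- doublet_scores(cells, expected_rate = 0.025, seed = 103L, n_pcs = 20)
truth <- cells$cell_meta$is_doublet
cat(sprintf("doublet calls: %d (planted %d); call precision %.2f\n",
            sum(ds$is_doublet_call), sum(truth),
            mean(truth[ds$is_doublet_call])))
keep <- qc$report$overall_pass & !ds$is_doublet_call
filt <- subset_cells(cells, which(keep))

nm <- normalize_log(filt)
emb <- pca_embed(nm, n_pcs = 20)
clusters <- cluster_graph(emb$coords, k_graph = 20, resolution = 0.6, seed = 104L)
labels <- annotate_by_markers(lineage_signatures(), nm, clusters)
filt$cell_meta$cluster <- unname(clusters[filt$cell_ids])
filt$cell_meta$celltype_called <- unname(labels[as.character(filt$cell_meta$cluster)])
acc <- mean(filt$cell_meta$celltype_called == filt$cell_meta$celltype)
cat(sprintf("clusters: %d; marker-based annotation agrees with ground truth for %.1f%% of cells\n",
            length(unique(clusters)), 100 * acc))

markers <- find_markers(nm, clusters)
write.table(markers, "results/cluster_markers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

filt$cell_meta$celltype <- filt$cell_meta$celltype_called
fr <- cell_fractions(filt)
write.table(fr, "results/cell_fractions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
tests <- compare_fractions(fr)
write.table(tests, "results/fraction_tests.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
myl <- fr[fr$lineage == "myeloid", ]
cat(sprintf("myeloid fraction: responder %.1f%% vs nonresponder %.1f%% (adj p = %.3g)\n",
            100 * mean(myl$fraction[myl$group == "responder"]),
            100 * mean(myl$fraction[myl$group == "nonresponder"]),
            tests$p_adj[tests$lineage == "myeloid"]))

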