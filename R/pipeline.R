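# End-to-end orchestration: one seeded run from raw (or simulated) counts to
# regulon modules, gating/mapping, and fraction statistics, with a manifest.

#' Run the full workflow on a CellMatrix
#'
#' Executes QC, normalization, PCA + graph clustering, marker-based
#' annotation, regulon activity scoring, CSI module detection, myeloid
#' gating with atlas construction, and the per-sample fraction comparison.
#' Every stage derives its RNG seed from the single global seed, and all
#' stage outputs are written as TSV under `out_dir` with a JSON manifest of
#' content hashes, so a rerun with identical inputs and seed reproduces the
#' hashes bit for bit.
#'
#' @param m a `CellMatrix` (e.g. from [simulate_cells()] or
#'   [read_cell_matrix()]).
#' @param regulons named list of `Regulon`s to score (default: the packaged
#'   PPARG regulon).
#' @param out_dir output directory.
#' @param seed global integer seed.
#' @param thresholds `QCThresholds`.
#' @param n_pcs,k_graph,resolution clustering parameters.
#' @param signatures lineage marker signatures for annotation.
#' @param n_atlas_clusters atlas clusters built from the gated myeloid cells
#'   (skipped with a note when too few cells pass the gate).
#' @return invisibly, a list with the stage results and the manifest path.
#' @export
run_pipeline <- function(m, regulons = list(PPARG = pparg_regulon()),
                         out_dir, seed = 1L,
                         thresholds = qc_thresholds(),
                         n_pcs = 20L, k_graph = 20L, resolution = 0.6,
                         signatures = lineage_signatures(),
                         n_atlas_clusters = 14L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  qc <- qc_filter(m, thresholds)
  emit(qc$report, "qc_report.tsv")
  filt <- qc$filtered
  nm <- normalize_log(filt)

  emb <- pca_embed(nm, n_pcs = n_pcs)
  clusters <- cluster_graph(emb$coords, k_graph = k_graph,
                            resolution = resolution,
                            seed = derive_seed(seed, "cluster"))
  labels <- annotate_by_markers(signatures, nm, clusters)
  filt$cell_meta$cluster <- unname(clusters[filt$cell_ids])
  filt$cell_meta$celltype <- unname(labels[as.character(filt$cell_meta$cluster)])
  emit(filt$cell_meta, "cell_annotation.tsv")

  markers <- find_markers(nm, clusters)
  emit(markers, "cluster_markers.tsv")

  ras <- aucell(filt, regulons)
  emit(data.frame(cell_id = rownames(ras$scores), ras$scores,
                  check.names = FALSE), "regulon_activity.tsv")
  rss <- regulon_specificity(ras, setNames(filt$cell_meta$celltype, filt$cell_ids))
  emit(rss, "regulon_specificity.tsv")

  modules <- NULL
  if (ncol(ras$scores) >= 3 && all(apply(ras$scores, 2, sd) > 0)) {
    cm <- csi(ras)
    emit(data.frame(regulon = rownames(cm$values), cm$values,
                    check.names = FALSE), "csi_matrix.tsv")
    modules <- detect_modules(cm, n_modules = min(3L, ncol(ras$scores)))
    emit(data.frame(regulon = names(modules$module), module = modules$module),
         "regulon_modules.tsv")
    emit(csi_network(cm), "csi_network.tsv")
  }

  gate <- gate_myeloid(nm)
  emit(gate$scores, "gate_scores.tsv")
  atlas <- NULL
  if (length(gate$cell_ids) >= n_atlas_clusters * 5) {
    keep <- match(gate$cell_ids, nm$cell_ids)
    myeloid_nm <- normalized_matrix(nm$values[, keep, drop = FALSE],
                                    nm$transform_tag)
    atlas <- build_reference(myeloid_nm, regulons[[1]],
                             n_clusters = n_atlas_clusters,
                             n_pcs = min(n_pcs, length(gate$cell_ids) - 1L),
                             seed = derive_seed(seed, "atlas"))
    write_reference(atlas, file.path(out_dir, "atlas"))
    outputs <- c(outputs, list.files(file.path(out_dir, "atlas"),
                                     full.names = TRUE))
  }

  fractions <- cell_fractions(filt)
  emit(fractions, "cell_fractions.tsv")
  stats <- tryCatch(compare_fractions(fractions), error = function(e) NULL)
  if (!is.null(stats)) emit(stats, "fraction_tests.tsv")

  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(seed = seed, outputs = manifest),
                       manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(qc = qc, normalized = nm, clusters = clusters,
                 annotation = labels, markers = markers, ras = ras,
                 rss = rss, modules = modules, atlas = atlas,
                 fractions = fractions, fraction_tests = stats,
                 manifest = manifest_path))
}
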