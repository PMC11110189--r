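# Marker-based myeloid gating, reference-atlas construction, query mapping,
# and the end-to-end regulon response report.

#' Gating specification for myeloid cells
#'
#' Cells pass when the rank-based activity of the positive marker set
#' (default CD14+) exceeds `pos_threshold` and that of the negative set
#' (default FCER1A-) is at most `neg_threshold`. Single-gene sets degrade
#' to rank-threshold indicators: the score is positive exactly when the
#' marker lies in the top rank window.
#'
#' @param positive_markers,negative_markers disjoint gene sets.
#' @param pos_threshold,neg_threshold score thresholds in [0,1]; defaults 0.
#' @param knn_smooth majority-vote smoothing neighbourhood in PC space
#'   (0 = off).
#' @return an object of class `GateSpec`.
#' @export
gate_spec <- function(positive_markers = "CD14", negative_markers = "FCER1A",
                      pos_threshold = 0, neg_threshold = 0, knn_smooth = 0L) {
  if (length(intersect(positive_markers, negative_markers))) {
    stopf("positive and negative marker sets must be disjoint")
  }
  assert_scalar_number(pos_threshold, "pos_threshold", 0, 1)
  assert_scalar_number(neg_threshold, "neg_threshold", 0, 1)
  assert_scalar_number(knn_smooth, "knn_smooth", lower = 0)
  structure(list(positive_markers = positive_markers,
                 negative_markers = negative_markers,
                 pos_threshold = pos_threshold, neg_threshold = neg_threshold,
                 knn_smooth = as.integer(knn_smooth)),
            class = "GateSpec")
}

#' Gate myeloid cells by positive/negative markers
#'
#' @param nm a `NormalizedMatrix` (or `CellMatrix`; scoring is rank-based).
#' @param spec a `GateSpec`.
#' @param threshold_fraction rank window for the marker scores (default 0.05).
#' @return list with `cell_ids` (passing cells), and a data.frame `scores`
#'   (`cell_id`, `pos_score`, `neg_score`, `pass`).
#' @export
gate_myeloid <- function(nm, spec = gate_spec(), threshold_fraction = 0.05) {
  gene_ids <- nm$gene_ids
  pos <- intersect(spec$positive_markers, gene_ids)
  if (!length(pos)) {
    stopf("no positive marker (%s) present in the matrix",
          paste(spec$positive_markers, collapse = ", "))
  }
  neg <- intersect(spec$negative_markers, gene_ids)
  regs <- list(pos = regulon(".gate_pos", pos))
  if (length(neg)) {
    regs$neg <- regulon(".gate_neg", neg)
  } else if (length(spec$negative_markers)) {
    warnf("no negative marker present; negative criterion skipped")
  }
  ras <- aucell(nm, regs, threshold_fraction = threshold_fraction)
  pos_score <- setNames(ras$scores[, "pos"], rownames(ras$scores))
  neg_score <- if (length(neg)) ras$scores[, "neg"] else rep(0, length(pos_score))
  pass <- pos_score > spec$pos_threshold & neg_score <= spec$neg_threshold
  if (spec$knn_smooth > 0 && sum(pass) > 0) {
    emb <- pca_embed(if (inherits(nm, "CellMatrix")) normalize_log(nm) else nm,
                     n_pcs = min(20L, length(gene_ids) - 1L))
    nn <- knn_index(emb$coords, emb$coords, spec$knn_smooth + 1L,
                    exclude_self = TRUE)
    votes <- rowMeans(matrix(pass[nn[, seq_len(spec$knn_smooth), drop = FALSE]],
                             nrow = nrow(nn)))
    pass <- votes > 0.5
  }
  ids <- names(pos_score)
  list(cell_ids = ids[pass],
       scores = data.frame(cell_id = ids, pos_score = pos_score,
                           neg_score = neg_score, pass = pass,
                           stringsAsFactors = FALSE))
}

#' Build a myeloid reference atlas
#'
#' Scales genes (storing means/sds), computes PC loadings, partitions the
#' reference cells by seeded k-means (best of 10 restarts), and computes the
#' per-cluster median regulon activity. Cluster labels are integers
#' 1..n_clusters by decreasing size (the roman I, II, ... of reports);
#' clusters whose median activity exceeds `high_score_cutoff` are flagged
#' response-associated.
#'
#' @param myeloid_nm a `NormalizedMatrix` of gated myeloid cells.
#' @param pparg a `Regulon` scored for the per-cluster medians (activity is
#'   computed on `myeloid_nm` ranks).
#' @param n_clusters number of atlas clusters (default 14, >= 2).
#' @param n_pcs PCs retained (default 20).
#' @param n_hvg number of highly-variable genes (by variance of the
#'   normalized values) the atlas is built on (default 200; `NULL` keeps all
#'   genes). Restricting the feature space keeps query projections on the
#'   same scale as the reference coordinates when cells are few relative to
#'   genes; label transfer degrades markedly without it.
#' @param seed RNG seed for k-means.
#' @param high_score_cutoff median-activity cutoff flagging response
#'   clusters (default 0.50).
#' @param threshold_fraction rank window for the activity scores.
#' @return an object of class `ReferenceAtlas`.
#' @export
build_reference <- function(myeloid_nm, pparg, n_clusters = 14L, n_pcs = 20L,
                            n_hvg = 200L, seed = 1L, high_score_cutoff = 0.50,
                            threshold_fraction = 0.05) {
  stopifnot(inherits(myeloid_nm, "NormalizedMatrix"), inherits(pparg, "Regulon"))
  if (n_clusters < 2) stopf("n_clusters must be >= 2")
  n_cells <- length(myeloid_nm$cell_ids)
  if (n_cells < n_clusters * 5) {
    stopf("need at least %d cells for %d clusters", n_clusters * 5, n_clusters)
  }
  pca_nm <- myeloid_nm
  if (!is.null(n_hvg) && n_hvg < length(myeloid_nm$gene_ids)) {
    v <- apply(as_dense(myeloid_nm$values), 1, var)
    hvg <- myeloid_nm$gene_ids[order(-v)[seq_len(n_hvg)]]
    pca_nm <- normalized_matrix(myeloid_nm$values[hvg, , drop = FALSE],
                                myeloid_nm$transform_tag)
  }
  emb <- pca_embed(pca_nm, n_pcs = n_pcs)
  km <- with_seed(seed, kmeans(emb$coords, centers = n_clusters, nstart = 10,
                               iter.max = 50))
  sizes <- sort(table(km$cluster), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  labels <- setNames(as.integer(relabel[as.character(km$cluster)]),
                     myeloid_nm$cell_ids)
  centroids <- km$centers[as.integer(names(sizes)), , drop = FALSE]
  rownames(centroids) <- seq_len(n_clusters)
  act <- aucell(myeloid_nm, pparg, threshold_fraction = threshold_fraction)
  med <- vapply(seq_len(n_clusters), function(cl) {
    median(act$scores[labels == cl, 1])
  }, numeric(1))
  response <- which(med > high_score_cutoff)
  if (!length(response)) warnf("no cluster has median activity above %.2f", high_score_cutoff)
  structure(list(genes = emb$genes_used, gene_means = emb$gene_means,
                 gene_sds = emb$gene_sds, loadings = emb$loadings,
                 ref_coords = emb$coords, labels = labels,
                 centroids = centroids, median_activity = med,
                 response_associated_clusters = as.integer(response),
                 high_score_cutoff = high_score_cutoff,
                 regulon = pparg, n_clusters = as.integer(n_clusters),
                 n_hvg = if (is.null(n_hvg)) NA_integer_ else as.integer(n_hvg),
                 threshold_fraction = threshold_fraction, seed = seed),
            class = "ReferenceAtlas")
}

#' @method print ReferenceAtlas
#' @export
print.ReferenceAtlas <- function(x, ...) {
  cat(sprintf(paste0("ReferenceAtlas: %d cells, %d genes, %d clusters; ",
                     "response-associated: %s\n"),
              nrow(x$ref_coords), length(x$genes), x$n_clusters,
              paste(x$response_associated_clusters, collapse = ", ")))
  invisible(x)
}

#' Map query cells onto a reference atlas
#'
#' Query genes are intersected with the atlas genes, scaled by the atlas
#' means/sds (genes absent from the query are imputed at 0 after scaling,
#' i.e. at the reference mean), projected onto the atlas loadings, and each
#' query cell takes the majority cluster label among its `k_transfer`
#' nearest reference cells; confidence is the majority fraction.
#'
#' @param atlas a `ReferenceAtlas`.
#' @param query_nm a `NormalizedMatrix` (same transform as the reference).
#' @param k_transfer neighbours for label transfer (default 15).
#' @return data.frame with `cell_id`, `cluster`, `confidence`.
#' @export
map_query <- function(atlas, query_nm, k_transfer = 15L) {
  stopifnot(inherits(atlas, "ReferenceAtlas"), inherits(query_nm, "NormalizedMatrix"))
  shared <- intersect(atlas$genes, query_nm$gene_ids)
  coverage <- length(shared) / length(atlas$genes)
  if (coverage < 0.5) {
    stopf("query covers only %.1f%% of the %d atlas genes (need >= 50%%)",
          100 * coverage, length(atlas$genes))
  }
  x <- matrix(0, length(atlas$genes), length(query_nm$cell_ids),
              dimnames = list(atlas$genes, query_nm$cell_ids))
  x[shared, ] <- as_dense(query_nm$values)[shared, , drop = FALSE]
  xs <- (x - atlas$gene_means) / atlas$gene_sds
  xs[setdiff(atlas$genes, shared), ] <- 0        # impute at reference mean
  coords <- crossprod(xs, atlas$loadings)
  k <- min(as.integer(k_transfer), nrow(atlas$ref_coords))
  nn <- knn_index(atlas$ref_coords, coords, k)
  lab <- matrix(atlas$labels[nn], nrow = nrow(nn))
  assign_one <- function(r) {
    tab <- sort(table(r), decreasing = TRUE)
    c(as.integer(names(tab)[1]), tab[[1]] / length(r))
  }
  res <- t(apply(lab, 1, assign_one))
  data.frame(cell_id = query_nm$cell_ids, cluster = as.integer(res[, 1]),
             confidence = res[, 2], stringsAsFactors = FALSE)
}

#' End-to-end regulon response report for a query dataset
#'
#' Runs the deployed procedure on a raw query count matrix: QC filter,
#' normalization, myeloid gating, per-cell regulon activity, reference
#' mapping, and per-cluster fraction reporting. The headline quantity is
#' the fraction of gated myeloid cells mapped into the atlas'
#' response-associated clusters.
#'
#' @param raw_query a `CellMatrix` of raw UMI counts.
#' @param atlas a `ReferenceAtlas`.
#' @param pparg the `Regulon` to score (defaults to the atlas' regulon).
#' @param spec a `GateSpec`.
#' @param thresholds `QCThresholds` for the QC stage.
#' @param k_transfer neighbours for label transfer.
#' @return an object of class `ResponseReport`: `n_query_cells`, `n_qc_pass`,
#'   `n_myeloid`, `cluster_fractions` (sums to 1 when `n_myeloid > 0`),
#'   `fraction_in_response_clusters` (NA when no myeloid cells),
#'   `activity_median`, `activity_iqr`, and `parameters`.
#' @export
pparg_report <- function(raw_query, atlas, pparg = atlas$regulon,
                         spec = gate_spec(), thresholds = qc_thresholds(),
                         k_transfer = 15L) {
  stopifnot(inherits(raw_query, "CellMatrix"))
  qc <- qc_filter(raw_query, thresholds)
  params <- list(qc = unclass(thresholds), gate = unclass(spec),
                 k_transfer = k_transfer, atlas_seed = atlas$seed,
                 threshold_fraction = atlas$threshold_fraction,
                 response_clusters = atlas$response_associated_clusters)
  empty <- function(n_pass) {
    structure(list(n_query_cells = length(raw_query$cell_ids),
                   n_qc_pass = n_pass, n_myeloid = 0L,
                   cluster_fractions = setNames(rep(NA_real_, atlas$n_clusters),
                                                seq_len(atlas$n_clusters)),
                   fraction_in_response_clusters = NA_real_,
                   activity_median = NA_real_, activity_iqr = NA_real_,
                   mapping = NULL, parameters = params),
              class = "ResponseReport")
  }
  if (!length(qc$filtered$cell_ids)) return(empty(0L))
  nm <- normalize_log(qc$filtered)
  gate <- gate_myeloid(nm, spec, threshold_fraction = atlas$threshold_fraction)
  if (!length(gate$cell_ids)) return(empty(length(qc$filtered$cell_ids)))
  keep <- match(gate$cell_ids, nm$cell_ids)
  myeloid_nm <- normalized_matrix(nm$values[, keep, drop = FALSE], nm$transform_tag)
  act <- aucell(myeloid_nm, pparg, threshold_fraction = atlas$threshold_fraction)
  mapped <- map_query(atlas, myeloid_nm, k_transfer = k_transfer)
  mapped$activity <- act$scores[mapped$cell_id, 1]
  frac <- as.numeric(table(factor(mapped$cluster, levels = seq_len(atlas$n_clusters)))) /
    nrow(mapped)
  names(frac) <- seq_len(atlas$n_clusters)
  structure(list(n_query_cells = length(raw_query$cell_ids),
                 n_qc_pass = length(qc$filtered$cell_ids),
                 n_myeloid = length(gate$cell_ids),
                 cluster_fractions = frac,
                 fraction_in_response_clusters =
                   sum(frac[as.character(atlas$response_associated_clusters)]),
                 activity_median = median(act$scores[, 1]),
                 activity_iqr = unname(diff(quantile(act$scores[, 1], c(0.25, 0.75)))),
                 mapping = mapped, parameters = params),
            class = "ResponseReport")
}

#' @method print ResponseReport
#' @export
print.ResponseReport <- function(x, ...) {
  cat(sprintf("ResponseReport: %d cells -> %d post-QC -> %d myeloid\n",
              x$n_query_cells, x$n_qc_pass, x$n_myeloid))
  if (x$n_myeloid > 0) {
    cat(sprintf("  fraction in response-associated clusters: %.3f\n",
                x$fraction_in_response_clusters))
    cat(sprintf("  regulon activity median %.3f (IQR %.3f)\n",
                x$activity_median, x$activity_iqr))
  } else {
    cat("  no myeloid cells gated; fractions undefined\n")
  }
  invisible(x)
}

#' Serialize a reference atlas to a directory of TSV files + JSON manifest
#'
#' @param atlas a `ReferenceAtlas`.
#' @param dir output directory.
#' @export
write_reference <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, col.names = NA)
  wt(data.frame(mean = atlas$gene_means, sd = atlas$gene_sds,
                row.names = atlas$genes), "scaling.tsv")
  wt(atlas$loadings, "loadings.tsv")
  wt(atlas$ref_coords, "ref_coords.tsv")
  wt(data.frame(label = atlas$labels, row.names = names(atlas$labels)),
     "labels.tsv")
  wt(atlas$centroids, "centroids.tsv")
  write_gene_sets(list(atlas$regulon), file.path(dir, "regulon.gmt"))
  jsonlite::write_json(
    list(n_clusters = atlas$n_clusters,
         median_activity = atlas$median_activity,
         response_associated_clusters = atlas$response_associated_clusters,
         high_score_cutoff = atlas$high_score_cutoff,
         threshold_fraction = atlas$threshold_fraction, seed = atlas$seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a reference atlas written by [write_reference()]
#'
#' @param dir atlas directory.
#' @return a `ReferenceAtlas`.
#' @export
read_reference <- function(dir) {
  rd <- function(f) as.matrix(read.delim(file.path(dir, f), row.names = 1,
                                         check.names = FALSE))
  scaling <- rd("scaling.tsv")
  loadings <- rd("loadings.tsv")
  coords <- rd("ref_coords.tsv")
  labels <- rd("labels.tsv")
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  structure(list(genes = rownames(scaling),
                 gene_means = setNames(scaling[, "mean"], rownames(scaling)),
                 gene_sds = setNames(scaling[, "sd"], rownames(scaling)),
                 loadings = loadings, ref_coords = coords,
                 labels = setNames(as.integer(labels[, 1]), rownames(labels)),
                 centroids = rd("centroids.tsv"),
                 median_activity = man$median_activity,
                 response_associated_clusters = as.integer(man$response_associated_clusters),
                 high_score_cutoff = man$high_score_cutoff,
                 regulon = read_gene_sets(file.path(dir, "regulon.gmt"))[[1]],
                 n_clusters = as.integer(man$n_clusters),
                 threshold_fraction = man$threshold_fraction, seed = man$seed),
            class = "ReferenceAtlas")
}
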