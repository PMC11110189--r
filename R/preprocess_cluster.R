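# Normalization, PCA, SNN graph clustering, marker detection, lineage
# annotation, and per-sample cell-type fractions.

#' Library-size normalize and log2-transform
#'
#' `value(g, c) = log2(1 + counts(g, c) / total(c) * scale)`; zeros map to
#' zero, so within-cell expression ranks are preserved exactly.
#'
#' @param m a `CellMatrix`.
#' @param scale library-size scale factor (default 1e4).
#' @return a `NormalizedMatrix` (sparse) with `transform_tag`
#'   `"lognorm_log2_scale<scale>"`.
#' @export
normalize_log <- function(m, scale = 1e4) {
  stopifnot(inherits(m, "CellMatrix"))
  total <- Matrix::colSums(m$counts)
  if (any(total == 0)) {
    stopf("cell(s) with zero total UMIs (should have failed QC): %s",
          paste(head(m$cell_ids[total == 0], 5), collapse = ", "))
  }
  v <- m$counts
  v@x <- log2(1 + v@x / rep.int(total, diff(v@p)) * scale)
  normalized_matrix(v, sprintf("lognorm_log2_scale%g", scale))
}

#' PCA embedding of cells
#'
#' Genes are centered and unit-scaled (sd floored at `sd_floor`) before the
#' decomposition; zero-variance genes are dropped. Per-component signs are
#' fixed by making the largest-magnitude gene loading positive, so repeated
#' runs are bit-identical.
#'
#' @param nm a `NormalizedMatrix`.
#' @param n_pcs number of components (default 20).
#' @param sd_floor lower bound applied to per-gene standard deviations.
#' @return list with `coords` (cells x n_pcs), `loadings` (genes x n_pcs),
#'   `gene_means`, `gene_sds`, `genes_used`, `sdev`.
#' @export
pca_embed <- function(nm, n_pcs = 20L, sd_floor = 1e-8) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  x <- as_dense(nm$values)
  mu <- rowMeans(x)
  sdv <- apply(x, 1, sd)
  keep <- sdv > 0
  if (sum(keep) < n_pcs) stopf("n_pcs = %d exceeds the %d genes with nonzero variance",
                               n_pcs, sum(keep))
  if (n_pcs > min(dim(x))) stopf("n_pcs = %d exceeds matrix dimensions", n_pcs)
  x <- x[keep, , drop = FALSE]
  mu <- mu[keep]; sdv <- pmax(sdv[keep], sd_floor)
  xs <- (x - mu) / sdv
  sv <- svd(t(xs))                      # cells x genes
  k <- seq_len(n_pcs)
  load <- sv$v[, k, drop = FALSE]
  coords <- sv$u[, k, drop = FALSE] %*% diag(sv$d[k], n_pcs)
  # sign convention: largest-|loading| entry positive per component
  for (j in k) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) { load[, j] <- -load[, j]; coords[, j] <- -coords[, j] }
  }
  rownames(coords) <- nm$cell_ids
  rownames(load) <- nm$gene_ids[keep]
  list(coords = coords, loadings = load, gene_means = setNames(mu, rownames(load)),
       gene_sds = setNames(sdv, rownames(load)), genes_used = rownames(load),
       sdev = sv$d[k] / sqrt(max(1, ncol(x) - 1)))
}

# Shared-nearest-neighbour graph with Jaccard edge weights.
snn_graph <- function(coords, k_graph) {
  n <- nrow(coords)
  nn <- knn_index(coords, coords, k_graph + 1L, exclude_self = TRUE)
  nn <- cbind(seq_len(n), nn[, seq_len(k_graph), drop = FALSE])  # self-inclusive
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k_graph + 1L),
                              j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  shared <- as(shared, "TsparseMatrix")
  i <- shared@i + 1L; j <- shared@j + 1L; s <- shared@x
  keep <- i < j
  i <- i[keep]; j <- j[keep]; s <- s[keep]
  jac <- s / (2 * (k_graph + 1L) - s)
  keep <- jac > 1 / 15                  # prune weak SNN edges
  igraph::graph_from_data_frame(
    data.frame(from = i[keep], to = j[keep], weight = jac[keep]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
}

#' Graph-based clustering (SNN + Louvain)
#'
#' Builds a shared-nearest-neighbour graph with Jaccard edge weights over
#' the PC coordinates and partitions it by Louvain modularity optimisation
#' at the given resolution. Cells are processed in canonical cell-id order,
#' so the partition is invariant to input cell order; cluster ids are
#' relabelled 0..K-1 by decreasing size.
#'
#' @param coords cells x PCs matrix with cell ids as rownames.
#' @param k_graph neighbours per cell (>= 2; default 20).
#' @param resolution Louvain resolution (default 0.6).
#' @param seed RNG seed.
#' @return integer vector of cluster ids named by cell id.
#' @export
cluster_graph <- function(coords, k_graph = 20L, resolution = 0.6, seed = 1L) {
  if (k_graph < 2) stopf("k_graph must be >= 2")
  if (nrow(coords) < k_graph + 1) stopf("need at least k_graph + 1 cells")
  ids <- rownames(coords)
  if (is.null(ids)) stopf("coords must carry cell ids as rownames")
  ord <- order_ids(ids)
  g <- snn_graph(coords[ord, , drop = FALSE], k_graph)
  memb <- with_seed(seed,
    igraph::membership(igraph::cluster_louvain(g, resolution = resolution)))
  cl <- integer(length(ids))
  cl[ord] <- as.integer(memb)
  sizes <- sort(table(cl), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  setNames(relabel[as.character(cl)], ids)
}

#' Per-cluster marker genes (one-vs-rest Wilcoxon)
#'
#' For each cluster, genes expressed in at least `min_pct` of in-cluster or
#' out-of-cluster cells are tested in-vs-rest with a two-sided Wilcoxon
#' rank-sum test, BH-adjusted across genes within the cluster. Log2
#' fold-change is computed on de-logged (expm) means.
#'
#' @param nm a `NormalizedMatrix` (log2 scale).
#' @param clusters integer cluster ids named by cell id.
#' @param min_pct expression-fraction floor (default 0.25).
#' @return data.frame with `cluster`, `gene`, `log2fc`, `pct_in`, `pct_out`,
#'   `p`, `p_adj`, sorted by cluster then adjusted p.
#' @export
find_markers <- function(nm, clusters, min_pct = 0.25) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  clusters <- clusters[nm$cell_ids]
  if (length(unique(clusters)) < 2) stopf("need at least 2 clusters")
  x <- as_dense(nm$values)
  out <- list()
  for (cl in sort(unique(clusters))) {
    inside <- clusters == cl
    if (sum(inside) < 3) {
      warnf("cluster %s has fewer than 3 cells; skipped", cl)
      next
    }
    pct_in <- rowMeans(x[, inside, drop = FALSE] > 0)
    pct_out <- rowMeans(x[, !inside, drop = FALSE] > 0)
    test <- pct_in >= min_pct | pct_out >= min_pct
    genes <- which(test)
    if (!length(genes)) next
    p <- vapply(genes, function(g) {
      suppressWarnings(wilcox.test(x[g, inside], x[g, !inside])$p.value)
    }, numeric(1))
    mean_in <- rowMeans(2^x[genes, inside, drop = FALSE] - 1)
    mean_out <- rowMeans(2^x[genes, !inside, drop = FALSE] - 1)
    out[[as.character(cl)]] <- data.frame(
      cluster = cl, gene = nm$gene_ids[genes],
      log2fc = log2((mean_in + 1e-9) / (mean_out + 1e-9)),
      pct_in = pct_in[genes], pct_out = pct_out[genes],
      p = p, p_adj = p.adjust(p, "BH"), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$cluster, res$p_adj), ]
}

#' Annotate clusters by canonical marker signatures
#'
#' Each cluster is labelled with the lineage whose signature has the highest
#' mean normalized expression in that cluster; ties break alphabetically
#' with a warning.
#'
#' @param signatures named list of gene sets (`Regulon`s or character
#'   vectors), one per lineage.
#' @param nm a `NormalizedMatrix`.
#' @param clusters integer cluster ids named by cell id.
#' @return named character vector: lineage label per cluster id.
#' @export
annotate_by_markers <- function(signatures, nm, clusters) {
  stopifnot(inherits(nm, "NormalizedMatrix"), length(signatures) > 0)
  sets <- lapply(signatures, function(s) if (inherits(s, "Regulon")) s$targets else s)
  present <- lapply(sets, intersect, y = nm$gene_ids)
  empty <- names(present)[lengths(present) == 0]
  if (length(empty)) {
    warnf("signature(s) with no genes in the matrix are unassignable: %s",
          paste(empty, collapse = ", "))
    present <- present[lengths(present) > 0]
    if (!length(present)) stopf("no signature has genes in the matrix")
  }
  clusters <- clusters[nm$cell_ids]
  x <- as_dense(nm$values)
  labels <- character(0)
  for (cl in sort(unique(clusters))) {
    cols <- clusters == cl
    means <- vapply(present, function(g) mean(x[g, cols, drop = FALSE]), numeric(1))
    top <- sort(names(means)[means == max(means)])
    if (length(top) > 1) {
      warnf("cluster %s: tie between %s; using '%s'", cl,
            paste(top, collapse = ", "), top[1])
    }
    labels[as.character(cl)] <- top[1]
  }
  labels
}

#' Per-sample cell-lineage fractions
#'
#' Fractions per sample sum to 1 over lineages; sample-lineage entries with
#' fewer than `min_cells_per_lineage` cells are flagged for removal before
#' group testing (`kept = FALSE`).
#'
#' @param m a `CellMatrix` with `celltype` and `sample_id` metadata populated.
#' @param min_cells_per_lineage drop floor (default 10).
#' @return data.frame with `sample_id`, `lineage`, `n_cells_lineage`,
#'   `n_cells_total`, `fraction`, `group` (the sample's response label) and
#'   `kept`.
#' @export
cell_fractions <- function(m, min_cells_per_lineage = 10L) {
  stopifnot(inherits(m, "CellMatrix"))
  meta <- m$cell_meta
  ok <- !is.na(meta$celltype)
  dropped <- setdiff(unique(meta$sample_id), unique(meta$sample_id[ok]))
  if (length(dropped)) {
    warnf("sample(s) with zero annotated cells dropped: %s",
          paste(dropped, collapse = ", "))
  }
  meta <- meta[ok, , drop = FALSE]
  if (!nrow(meta)) stopf("no annotated cells")
  lineages <- sort(unique(meta$celltype))
  out <- list()
  for (sid in unique(meta$sample_id)) {
    sm <- meta[meta$sample_id == sid, , drop = FALSE]
    counts <- table(factor(sm$celltype, levels = lineages))
    out[[sid]] <- data.frame(
      sample_id = sid, lineage = lineages,
      n_cells_lineage = as.integer(counts), n_cells_total = nrow(sm),
      fraction = as.numeric(counts) / nrow(sm),
      group = sm$response[1], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$kept <- res$n_cells_lineage >= min_cells_per_lineage
  res
}

#' Compare lineage fractions between two groups
#'
#' One-sided unpaired Wilcoxon rank-sum test per lineage on the per-sample
#' fractions (after the minimum-cell filter), BH-adjusted across lineages.
#'
#' @param fractions output of [cell_fractions()].
#' @param group_high,group_low group labels; the alternative is
#'   `group_high > group_low`.
#' @return data.frame with `lineage`, `n_high`, `n_low`, `p`, `p_adj`.
#' @export
compare_fractions <- function(fractions, group_high = "responder",
                              group_low = "nonresponder") {
  f <- fractions[fractions$kept, , drop = FALSE]
  out <- list()
  for (lin in sort(unique(f$lineage))) {
    fl <- f[f$lineage == lin, , drop = FALSE]
    xh <- fl$fraction[fl$group == group_high]
    xl <- fl$fraction[fl$group == group_low]
    if (!length(xh) || !length(xl)) next
    p <- wilcoxon_one_sided(xh, xl, "greater")$p
    out[[lin]] <- data.frame(lineage = lin, n_high = length(xh),
                             n_low = length(xl), p = p,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stopf("no lineage has samples in both groups")
  rownames(res) <- NULL
  res$p_adj <- bh_fdr(res$p)
  res
}
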