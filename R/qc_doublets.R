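# Four-rule single-cell QC (expressed genes, mitochondrial and ribosomal UMI
# fractions, housekeeping UMI sum) and a simulation-based doublet score.

#' QC thresholds
#'
#' A cell is excluded when it has fewer than `min_genes` expressed genes,
#' more than `max_mito_fraction` of its UMIs on mitochondrial genes, more
#' than `max_ribo_fraction` on ribosomal genes, or a housekeeping UMI sum
#' (ACTB + GAPDH + MALAT1, on raw counts) below `min_housekeeping_umi`.
#' A housekeeping sum of exactly 1 passes.
#'
#' @param min_genes minimum expressed genes (default 500).
#' @param max_mito_fraction maximum mitochondrial UMI fraction (default 0.20).
#' @param max_ribo_fraction maximum ribosomal UMI fraction (default 0.50).
#' @param min_housekeeping_umi minimum housekeeping UMI sum (default 1).
#' @param housekeeping_genes symbols summed for the housekeeping score.
#' @param mito_prefix,ribo_prefixes symbol prefixes identifying the
#'   mitochondrial and ribosomal gene classes.
#' @return an object of class `QCThresholds`.
#' @export
qc_thresholds <- function(min_genes = 500L, max_mito_fraction = 0.20,
                          max_ribo_fraction = 0.50, min_housekeeping_umi = 1L,
                          housekeeping_genes = c("ACTB", "GAPDH", "MALAT1"),
                          mito_prefix = "MT-",
                          ribo_prefixes = c("RPS", "RPL")) {
  assert_scalar_number(min_genes, "min_genes", lower = 0)
  assert_scalar_number(max_mito_fraction, "max_mito_fraction", 0, 1)
  assert_scalar_number(max_ribo_fraction, "max_ribo_fraction", 0, 1)
  structure(list(min_genes = as.integer(min_genes),
                 max_mito_fraction = max_mito_fraction,
                 max_ribo_fraction = max_ribo_fraction,
                 min_housekeeping_umi = min_housekeeping_umi,
                 housekeeping_genes = housekeeping_genes,
                 mito_prefix = mito_prefix, ribo_prefixes = ribo_prefixes),
            class = "QCThresholds")
}

#' Filter cells by the four QC exclusion rules
#'
#' Fractions are UMIs of the gene class divided by the cell's total UMIs;
#' the housekeeping score is computed on raw UMIs.
#'
#' @param m a `CellMatrix` of raw UMI counts.
#' @param thresholds a `QCThresholds`.
#' @return a list with `filtered` (the `CellMatrix` of passing cells) and
#'   `report` (a data.frame with one row per input cell: per-criterion
#'   quantities, pass flags, and `overall_pass`).
#' @export
qc_filter <- function(m, thresholds = qc_thresholds()) {
  stopifnot(inherits(m, "CellMatrix"))
  t <- thresholds
  counts <- m$counts
  hk <- intersect(t$housekeeping_genes, m$gene_ids)
  if (!length(hk)) {
    stopf("none of the housekeeping genes (%s) is present; the housekeeping criterion is uncomputable",
          paste(t$housekeeping_genes, collapse = ", "))
  }
  total <- Matrix::colSums(counts)
  n_expr <- Matrix::colSums(counts > 0)
  is_mito <- startsWith(m$gene_ids, t$mito_prefix)
  is_ribo <- Reduce(`|`, lapply(t$ribo_prefixes, startsWith, x = m$gene_ids))
  mito_frac <- as.numeric(Matrix::colSums(counts[is_mito, , drop = FALSE])) /
    pmax(total, 1)
  ribo_frac <- as.numeric(Matrix::colSums(counts[is_ribo, , drop = FALSE])) /
    pmax(total, 1)
  hk_umi <- as.numeric(Matrix::colSums(counts[hk, , drop = FALSE]))
  pass_genes <- n_expr >= t$min_genes
  pass_mito <- mito_frac <= t$max_mito_fraction
  pass_ribo <- ribo_frac <= t$max_ribo_fraction
  pass_hk <- hk_umi >= t$min_housekeeping_umi
  overall <- pass_genes & pass_mito & pass_ribo & pass_hk
  report <- data.frame(cell_id = m$cell_ids, n_genes_expressed = as.integer(n_expr),
                       mito_fraction = mito_frac, ribo_fraction = ribo_frac,
                       housekeeping_umi = hk_umi, doublet_score = NA_real_,
                       pass_min_genes = pass_genes, pass_mito = pass_mito,
                       pass_ribo = pass_ribo, pass_housekeeping = pass_hk,
                       overall_pass = overall, stringsAsFactors = FALSE)
  list(filtered = subset_cells(m, which(overall)), report = report)
}

#' Simulation-based doublet scores
#'
#' Simulates artificial doublets as raw-count sums of uniformly sampled
#' observed cell pairs, co-embeds observed and simulated cells
#' (library-size normalization, log transform, PCA), and scores each
#' observed cell by the fraction of its k nearest neighbours in the
#' combined embedding that are simulated, rescaled by the
#' simulated-to-observed ratio so scores are comparable across settings.
#' Calls default to the top `expected_rate` quantile of scores.
#'
#' Cells are processed in a canonical order (by cell id), so the result is
#' invariant to gene and cell order given the seed.
#'
#' @param m a `CellMatrix` of raw UMI counts.
#' @param expected_rate expected doublet rate in [0,1) (default 0.025).
#' @param n_simulated_factor simulated doublets per observed cell (default 2).
#' @param k_neighbors neighbourhood size; default `round(0.5 * sqrt(n_cells))`.
#' @param n_pcs principal components of the co-embedding (default 30).
#' @param seed RNG seed.
#' @param threshold optional explicit score threshold overriding the
#'   expected-rate quantile.
#' @return data.frame with `cell_id`, `doublet_score`, `is_doublet_call`.
#' @export
doublet_scores <- function(m, expected_rate = 0.025, n_simulated_factor = 2,
                           k_neighbors = NULL, n_pcs = 30L, seed = 1L,
                           threshold = NULL) {
  stopifnot(inherits(m, "CellMatrix"))
  if (expected_rate < 0 || expected_rate >= 1) {
    stopf("expected_rate must be in [0, 1)")
  }
  n <- length(m$cell_ids)
  if (is.null(k_neighbors)) k_neighbors <- max(3L, round(0.5 * sqrt(n)))
  if (n < 2 * k_neighbors) stopf("need at least 2 * k_neighbors = %d cells", 2 * k_neighbors)
  ord <- order_ids(m$cell_ids)
  counts <- as_dense(m$counts)[, ord, drop = FALSE]
  n_sim <- max(1L, round(n_simulated_factor * n))
  with_seed(seed, {
    ia <- sample.int(n, n_sim, replace = TRUE)
    ib <- sample.int(n, n_sim, replace = TRUE)
    sim <- counts[, ia, drop = FALSE] + counts[, ib, drop = FALSE]
    all_counts <- cbind(counts, sim)
    tot <- colSums(all_counts)
    expr <- log1p(sweep(all_counts, 2, pmax(tot, 1), "/") * 1e4)
    keep <- apply(expr, 1, sd) > 0
    expr <- expr[keep, , drop = FALSE]
    x <- t(scale(t(expr)))            # center/scale genes over the joint set
    n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x) - 1L)
    sv <- svd(t(x), nu = n_pcs, nv = 0)
    emb <- sv$u[, seq_len(n_pcs), drop = FALSE] %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
    nn <- knn_index(emb, emb[seq_len(n), , drop = FALSE], k_neighbors + 1L,
                    exclude_self = TRUE)
    nn <- nn[, seq_len(k_neighbors), drop = FALSE]
    frac_sim <- rowMeans(nn > n)
    rho <- n_sim / n
    score <- frac_sim / (frac_sim + rho * (1 - frac_sim))  # odds rescale
  })
  score_by_cell <- numeric(n)
  score_by_cell[ord] <- score
  if (is.null(threshold)) {
    calls <- if (expected_rate == 0) rep(FALSE, n) else {
      score_by_cell >= quantile(score_by_cell, 1 - expected_rate, type = 1) &
        score_by_cell > 0
    }
  } else {
    calls <- score_by_cell > threshold
  }
  data.frame(cell_id = m$cell_ids, doublet_score = score_by_cell,
             is_doublet_call = calls, stringsAsFactors = FALSE)
}
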