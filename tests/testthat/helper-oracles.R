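# Independent brute-force oracles and small fixture builders shared by the
# suite. The oracles deliberately use explicit loops / enumeration and never
# call the implementation paths they check.

# Recovery-curve AUC by explicit curve enumeration.
aucell_oracle <- function(expr, gene_ids, targets, threshold_fraction) {
  G <- length(expr)
  Tw <- max(1L, floor(threshold_fraction * G))
  ord <- order(-expr, rank(gene_ids))        # ties: ascending gene id
  top <- gene_ids[ord]
  y <- vapply(seq_len(Tw), function(k) length(intersect(targets, top[seq_len(k)])),
              numeric(1))
  M <- min(length(intersect(targets, gene_ids)), Tw)
  if (M == 0) return(0)
  sum(y) / sum(pmin(seq_len(Tw), M))
}

# CSI by scalar double loop over partners, per pair.
csi_oracle <- function(scores) {
  N <- ncol(scores)
  out <- matrix(1, N, N, dimnames = list(colnames(scores), colnames(scores)))
  for (a in seq_len(N)) for (b in seq_len(N)) {
    if (a == b) next
    pab <- cor(scores[, a], scores[, b])
    count <- 0
    for (cc in seq_len(N)) {
      if (cc == a || cc == b) next
      if (cor(scores[, a], scores[, cc]) < pab &&
          cor(scores[, b], scores[, cc]) < pab) count <- count + 1
    }
    out[a, b] <- count / (N - 2)
  }
  out
}

# GSVA stages 2-3 for one sample by explicit walk; z is the gene-level
# statistic vector for that sample.
gsva_walk_oracle <- function(z, gene_ids, set_genes, tau = 1,
                             es_mode = "maxdiff") {
  N <- length(z)
  ord <- order(-z, rank(gene_ids))
  in_set <- gene_ids %in% set_genes
  w <- abs(N / 2 - seq_len(N) + 0.5)^tau     # weight at walk position
  wsum <- sum(w[which(in_set[ord])])
  dev <- 0; devs <- numeric(N)
  for (k in seq_len(N)) {
    g <- ord[k]
    if (in_set[g]) dev <- dev + w[k] / wsum else dev <- dev - 1 / sum(!in_set)
    devs[k] <- dev
  }
  if (es_mode == "maxdiff") max(c(0, devs)) + min(c(0, devs))
  else devs[which.max(abs(devs))]
}

# One-sided Wilcoxon p by exhaustive enumeration of rank assignments.
wilcoxon_enum_oracle <- function(x, y, alternative = "greater") {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  if (alternative == "greater") mean(us >= u_obs) else mean(us <= u_obs)
}

# AUROC of scores against binary labels (rank formula).
auroc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Small dense CellMatrix from a base matrix.
toy_cells <- function(mat, gene_ids = NULL, cell_ids = NULL, meta = NULL) {
  if (is.null(gene_ids)) gene_ids <- sprintf("g%02d", seq_len(nrow(mat)))
  if (is.null(cell_ids)) cell_ids <- sprintf("c%02d", seq_len(ncol(mat)))
  dimnames(mat) <- list(gene_ids, cell_ids)
  cell_matrix(mat, cell_meta = meta)
}

# Compact generator config for fast tests; `...` overrides the defaults.
small_config <- function(seed = 1L, ...) {
  args <- list(n_genes = 600L, n_cells_per_sample = 200L,
               n_samples_per_group = 2L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_config, args)
}

# All permutations of 1..n as a matrix (rows), n small.
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(setdiff(seq_len(n), k)[sub], nrow(sub)))
  }))
}
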