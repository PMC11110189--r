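# Gene set variation analysis for bulk RNA-seq: per-gene kernel-smoothed
# cross-sample expression CDFs followed by a per-sample weighted
# Kolmogorov-Smirnov random walk over the gene ranking.

gsva_stage1 <- function(x, kernel) {
  n <- ncol(x)
  z <- matrix(NA_real_, nrow(x), n, dimnames = dimnames(x))
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ]
    z[i, ] <- switch(kernel,
      gaussian = {
        h <- sd(xi) / 4
        colMeans(pnorm(outer(xi, xi, function(a, b) (b - a) / h)))
      },
      poisson = colMeans(matrix(ppois(rep(xi, each = n), rep(xi, times = n) + 0.5),
                                nrow = n)),
      none = colMeans(outer(xi, xi, "<=")))
  }
  z
}

# Weighted KS walk for one sample: `ord` is the gene order (decreasing z),
# `weight` the symmetrized rank statistic^tau, `in_set` logical per gene.
gsva_walk <- function(ord, weight, in_set, es_mode) {
  w <- weight[ord] * in_set[ord]
  pen <- (!in_set[ord]) / sum(!in_set)
  dev <- cumsum(w / sum(w) - pen)
  if (es_mode == "maxdiff") {
    max(c(0, dev)) + min(c(0, dev))
  } else {
    dev[which.max(abs(dev))]
  }
}

#' Gene set variation analysis scores
#'
#' Stage 1: per gene, a kernel-smoothed empirical CDF of its expression
#' across samples is evaluated at each sample (Gaussian kernel with
#' bandwidth sd/4 for continuous input, a Poisson kernel for integer
#' counts, or the plain ECDF with `kernel = "none"`). Stage 2: per sample,
#' genes are ranked by the CDF statistic in decreasing order and the rank is
#' symmetrized about the centre, `|N/2 - position + 1/2|`. Stage 3: a
#' weighted Kolmogorov-Smirnov random walk down the ranking with weight
#' `|r|^tau` for set genes and a uniform penalty for non-set genes; the
#' enrichment score is the maximum positive plus minimum negative deviation
#' (`es_mode = "maxdiff"`, default) or the largest absolute deviation with
#' its sign (`"twosided"`).
#'
#' @param bulk a `BulkMatrix` with >= 2 samples.
#' @param sets a `Regulon` or list of regulons/gene sets.
#' @param kernel `"auto"` (Poisson when all values are integers, Gaussian
#'   otherwise), `"gaussian"`, `"poisson"`, or `"none"`.
#' @param tau rank-weight exponent (default 1).
#' @param es_mode `"maxdiff"` (default) or `"twosided"`.
#' @return an object of class `GSVAResult`: `scores` (sets x samples) and
#'   `parameters`. Sets with no genes in the matrix get a row of NA with a
#'   warning; constant gene rows are dropped with a warning.
#' @export
gsva <- function(bulk, sets, kernel = c("auto", "gaussian", "poisson", "none"),
                 tau = 1, es_mode = c("maxdiff", "twosided")) {
  stopifnot(inherits(bulk, "BulkMatrix"))
  kernel <- match.arg(kernel)
  es_mode <- match.arg(es_mode)
  if (inherits(sets, "Regulon")) sets <- list(sets)
  sets <- lapply(sets, function(s) if (inherits(s, "Regulon")) s else regulon("set", s))
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- vapply(sets, `[[`, character(1), "tf")
  }
  x <- bulk$values
  if (ncol(x) < 2) stopf("the gene-level statistic is cross-sample; need >= 2 samples")
  if (kernel == "auto") {
    kernel <- if (all(x == round(x))) "poisson" else "gaussian"
  }
  const <- apply(x, 1, sd) == 0
  if (kernel == "gaussian" && any(const)) {
    warnf("%d constant gene row(s) dropped (bandwidth undefined)", sum(const))
    x <- x[!const, , drop = FALSE]
  }
  z <- gsva_stage1(x, kernel)
  N <- nrow(z)
  tie <- id_tiebreak(rownames(z))
  scores <- matrix(NA_real_, length(sets), ncol(z),
                   dimnames = list(names(sets), colnames(z)))
  in_set_list <- lapply(sets, function(s) rownames(z) %in% scoring_genes(s))
  empty <- vapply(in_set_list, function(v) !any(v), logical(1))
  if (any(empty)) warnf("set(s) with no matched genes: %s",
                        paste(names(sets)[empty], collapse = ", "))
  for (j in seq_len(ncol(z))) {
    ord <- order(-z[, j], tie)
    pos <- integer(N); pos[ord] <- seq_len(N)
    weight <- abs(N / 2 - pos + 0.5)^tau
    for (si in seq_along(sets)) {
      if (empty[si] || all(in_set_list[[si]])) next
      scores[si, j] <- gsva_walk(ord, weight, in_set_list[[si]], es_mode)
    }
  }
  structure(list(scores = scores,
                 parameters = list(kernel = kernel, tau = tau, es_mode = es_mode)),
            class = "GSVAResult")
}

#' Compare per-sample gene-set scores between two groups
#'
#' One-sided Wilcoxon rank-sum test (`group_high > group_low`) per set,
#' BH-adjusted across sets.
#'
#' @param res a `GSVAResult`.
#' @param groups group label per sample (aligned with score columns, or
#'   named by sample id).
#' @param group_high,group_low the two labels compared; each group needs
#'   >= 3 samples.
#' @return data.frame with `set`, `n_high`, `n_low`, `p`, `p_adj`.
#' @export
score_group_compare <- function(res, groups, group_high = "responder",
                                group_low = "nonresponder") {
  stopifnot(inherits(res, "GSVAResult"))
  if (!is.null(names(groups))) groups <- groups[colnames(res$scores)]
  if (length(groups) != ncol(res$scores)) {
    stopf("groups length does not match the number of samples")
  }
  hi <- which(groups == group_high); lo <- which(groups == group_low)
  if (length(hi) < 3 || length(lo) < 3) {
    stopf("each group needs >= 3 samples (have %d and %d)", length(hi), length(lo))
  }
  p <- vapply(rownames(res$scores), function(s) {
    wilcoxon_one_sided(res$scores[s, hi], res$scores[s, lo], "greater")$p
  }, numeric(1))
  data.frame(set = rownames(res$scores), n_high = length(hi),
             n_low = length(lo), p = p, p_adj = bh_fdr(p),
             row.names = NULL, stringsAsFactors = FALSE)
}
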