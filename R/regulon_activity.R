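# Rank-based regulon activity scoring: per-cell area under the gene-set
# recovery curve restricted to the top fraction of the expression ranking,
# plus binarization and regulon specificity scores.

#' Regulon activity scores (recovery-curve AUC)
#'
#' Per cell, genes are ranked by decreasing expression with ties broken by
#' ascending gene id (deterministic). With `T = max(1, floor(
#' threshold_fraction * n_genes))`, the recovery curve is
#' `y(k) = |targets in top-k|` for `k = 1..T`; the raw AUC is `sum(y)` and
#' the score is the raw AUC divided by its maximum
#' `sum_{k=1..T} min(k, min(|targets in matrix|, T))`, so scores lie in
#' [0,1]. Scores depend only on within-cell expression ranks, so any
#' strictly monotone per-cell transform of expression leaves them unchanged;
#' raw counts are the conventional input.
#'
#' @param m a `CellMatrix` or `NormalizedMatrix`.
#' @param regulons a `Regulon` or (named) list of regulons.
#' @param threshold_fraction top-rank window as a fraction of genes,
#'   in (0, 1] (default 0.05).
#' @return an object of class `RegulonActivityMatrix`: `scores`
#'   (cells x regulons), `threshold_fraction`, and empty binarization slots.
#' @export
aucell <- function(m, regulons, threshold_fraction = 0.05) {
  if (inherits(regulons, "Regulon")) regulons <- list(regulons)
  if (!length(regulons)) stopf("need at least one regulon")
  if (is.null(names(regulons)) || any(!nzchar(names(regulons)))) {
    names(regulons) <- vapply(regulons, `[[`, character(1), "tf")
  }
  assert_scalar_number(threshold_fraction, "threshold_fraction", 0, 1,
                       lower_open = TRUE)
  x <- if (inherits(m, "CellMatrix")) m$counts else m$values
  gene_ids <- rownames(x); cell_ids <- colnames(x)
  G <- nrow(x)
  Tw <- max(1L, as.integer(floor(threshold_fraction * G)))
  tie <- id_tiebreak(gene_ids)
  target_idx <- lapply(regulons, function(r) {
    idx <- match(intersect(scoring_genes(r), gene_ids), gene_ids)
    if (!length(idx)) warnf("regulon '%s': no scored gene present; scores set to 0", r$tf)
    idx
  })
  denom <- vapply(target_idx, function(idx) {
    M <- min(length(idx), Tw)
    if (M == 0) return(1)
    M * (M + 1) / 2 + (Tw - M) * M
  }, numeric(1))
  xd <- as_dense(x)
  scores <- matrix(0, ncol(xd), length(regulons),
                   dimnames = list(cell_ids, names(regulons)))
  ranks <- integer(G)
  for (ci in seq_len(ncol(xd))) {
    ord <- order(-xd[, ci], tie)
    ranks[ord] <- seq_len(G)
    for (ri in seq_along(target_idx)) {
      r <- ranks[target_idx[[ri]]]
      scores[ci, ri] <- sum(pmax(0L, Tw - r + 1L)) / denom[[ri]]
    }
  }
  structure(list(scores = scores, threshold_fraction = threshold_fraction,
                 thresholds = NULL, binary = NULL),
            class = "RegulonActivityMatrix")
}

#' @method print RegulonActivityMatrix
#' @export
print.RegulonActivityMatrix <- function(x, ...) {
  cat(sprintf("RegulonActivityMatrix: %d cells x %d regulons (top %.1f%% window)%s\n",
              nrow(x$scores), ncol(x$scores), 100 * x$threshold_fraction,
              if (is.null(x$binary)) "" else ", binarized"))
  invisible(x)
}

# Otsu threshold: maximize between-class variance over observed midpoints.
otsu_threshold <- function(v) {
  u <- sort(unique(v))
  if (length(u) < 2) return(Inf)
  cand <- (u[-1] + u[-length(u)]) / 2
  bcv <- vapply(cand, function(thr) {
    lo <- v <= thr
    w <- mean(lo)
    if (w == 0 || w == 1) return(-Inf)
    w * (1 - w) * (mean(v[lo]) - mean(v[!lo]))^2
  }, numeric(1))
  cand[which.max(bcv)]
}

# Two-component Gaussian mixture threshold: density intersection between the
# component means (falls back to their midpoint when no crossing exists).
gmm2_threshold <- function(v) {
  if (length(unique(v)) < 3) return(otsu_threshold(v))
  fit <- tryCatch(mclust::Mclust(v, G = 2, modelNames = "V", verbose = FALSE),
                  error = function(e) NULL)
  if (is.null(fit)) return(otsu_threshold(v))
  mu <- fit$parameters$mean
  sig <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sig) == 1) sig <- rep(sig, 2)
  pr <- fit$parameters$pro
  o <- order(mu); mu <- mu[o]; sig <- sig[o]; pr <- pr[o]
  if (diff(mu) < .Machine$double.eps) return(mu[1])
  f <- function(x) pr[1] * dnorm(x, mu[1], sig[1]) - pr[2] * dnorm(x, mu[2], sig[2])
  lo <- mu[1]; hi <- mu[2]
  if (sign(f(lo)) == sign(f(hi))) return(mean(mu))
  uniroot(f, c(lo, hi))$root
}

#' Binarize regulon activity scores
#'
#' Per-regulon thresholds by a two-component Gaussian mixture intersection
#' (`gmm2`, default), Otsu's between-class-variance criterion (`otsu`), or a
#' fixed constant; `binary = score > threshold`. A constant score column
#' gets threshold `+Inf` (all inactive) with a warning.
#'
#' @param ras a `RegulonActivityMatrix`.
#' @param method one of `"gmm2"`, `"otsu"`, `"fixed"`.
#' @param fixed_value threshold used when `method = "fixed"`.
#' @return the `RegulonActivityMatrix` with `thresholds` and `binary` filled.
#' @export
binarize <- function(ras, method = c("gmm2", "otsu", "fixed"),
                     fixed_value = NULL) {
  stopifnot(inherits(ras, "RegulonActivityMatrix"))
  method <- match.arg(method)
  if (method == "fixed" && is.null(fixed_value)) stopf("fixed_value required")
  thr <- vapply(colnames(ras$scores), function(rn) {
    v <- ras$scores[, rn]
    if (sd(v) == 0) {
      warnf("regulon '%s' has constant scores; all cells set inactive", rn)
      return(Inf)
    }
    switch(method, fixed = fixed_value, otsu = otsu_threshold(v),
           gmm2 = gmm2_threshold(v))
  }, numeric(1))
  ras$thresholds <- thr
  ras$binary <- sweep(ras$scores, 2, thr, ">")
  ras
}

# Jensen-Shannon divergence (base-2 logs) between probability vectors.
jsd2 <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  # clamp away floating-point drift at the 0 and 1 boundaries
  min(max((kl(p, m) + kl(q, m)) / 2, 0), 1)
}

#' Regulon specificity scores
#'
#' `RSS(r, t) = 1 - sqrt(JSD(p_r, q_t))` with base-2 Jensen-Shannon
#' divergence, where `p_r` is the regulon's activity vector over cells
#' normalized to sum 1 and `q_t` the normalized indicator of membership in
#' cell type `t`. A regulon with all-zero scores gets RSS 0 with a warning.
#'
#' @param ras a `RegulonActivityMatrix`.
#' @param celltypes character cell-type label per cell (aligned with the
#'   score rows, or named by cell id); must be non-missing, >= 2 types.
#' @return data.frame with `regulon`, `celltype`, `rss`, and the per-type
#'   `rank` of each regulon (1 = most specific).
#' @export
regulon_specificity <- function(ras, celltypes) {
  stopifnot(inherits(ras, "RegulonActivityMatrix"))
  if (!is.null(names(celltypes))) celltypes <- celltypes[rownames(ras$scores)]
  if (length(celltypes) != nrow(ras$scores)) {
    stopf("celltypes length does not match the number of cells")
  }
  if (anyNA(celltypes)) stopf("unknown (missing) cell type label")
  types <- sort(unique(celltypes))
  if (length(types) < 2) stopf("need at least 2 cell types")
  if (any(ras$scores < 0)) stopf("scores must be non-negative")
  out <- list()
  for (rn in colnames(ras$scores)) {
    v <- ras$scores[, rn]
    if (sum(v) == 0) {
      warnf("regulon '%s' has zero total activity; RSS set to 0", rn)
      rss <- setNames(rep(0, length(types)), types)
    } else {
      p <- v / sum(v)
      rss <- vapply(types, function(t) {
        q <- as.numeric(celltypes == t)
        1 - sqrt(jsd2(p, q / sum(q)))
      }, numeric(1))
    }
    out[[rn]] <- data.frame(regulon = rn, celltype = types, rss = rss,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$rank <- NA_integer_
  for (t in types) {
    rows <- res$celltype == t
    res$rank[rows] <- rank(-res$rss[rows], ties.method = "min")
  }
  res
}
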