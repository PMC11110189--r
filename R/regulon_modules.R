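# Connection specificity index, regulon module detection, module activity
# scores, and the CSI association network.

#' Connection specificity index matrix
#'
#' Step 1: Pearson correlation (PCC) between every pair of regulon activity
#' vectors. Step 2: for a pair (A, B),
#' `CSI(A, B) = |{C not in {A, B} : PCC(A, C) < PCC(A, B) and
#' PCC(B, C) < PCC(A, B)}| / (N - 2)`. The diagonal is fixed at 1.
#'
#' @param ras a `RegulonActivityMatrix` with >= 3 regulons; every score
#'   column must be non-constant (PCC undefined otherwise).
#' @return an object of class `CSIMatrix`: `values` (symmetric, in [0,1],
#'   unit diagonal) and the source `pcc` matrix.
#' @export
csi <- function(ras) {
  scores <- if (inherits(ras, "RegulonActivityMatrix")) ras$scores else as.matrix(ras)
  N <- ncol(scores)
  if (N < 3) stopf("need at least 3 regulons")
  sds <- apply(scores, 2, sd)
  if (any(sds == 0)) {
    stopf("constant activity column(s), PCC undefined: %s",
          paste(colnames(scores)[sds == 0], collapse = ", "))
  }
  pcc <- cor(scores)
  structure(list(values = csi_from_pcc(pcc), pcc = pcc), class = "CSIMatrix")
}

# CSI from a precomputed PCC matrix. The partner set excludes A and B
# themselves; both partner correlations must fall strictly below PCC(A, B).
csi_from_pcc <- function(pcc) {
  N <- nrow(pcc)
  vals <- matrix(1, N, N, dimnames = dimnames(pcc))
  for (a in seq_len(N - 1)) {
    for (b in (a + 1):N) {
      others <- setdiff(seq_len(N), c(a, b))
      n_lower <- sum(pcc[a, others] < pcc[a, b] & pcc[b, others] < pcc[a, b])
      vals[a, b] <- vals[b, a] <- n_lower / (N - 2)
    }
  }
  vals
}

#' Detect regulon modules by hierarchical clustering of the CSI matrix
#'
#' Rows of the CSI matrix are the feature vectors; pairwise Euclidean
#' distances feed agglomerative clustering, and the tree is cut at
#' `n_modules`. Module ids are ordered by decreasing size. A silhouette
#' width per candidate cut is returned as a suggestion, not enforced.
#'
#' @param csi_mat a `CSIMatrix`.
#' @param n_modules number of modules to cut, in [1, N].
#' @param linkage `"average"` (default), `"complete"`, or `"ward"`.
#' @return an object of class `RegulonModuleSet`: `module` (integer per
#'   regulon, named), `members` (list per module), `hclust`, and
#'   `silhouette` (named vector over candidate cuts 2..min(N-1, 10)).
#' @export
detect_modules <- function(csi_mat, n_modules, linkage = c("average", "complete", "ward")) {
  stopifnot(inherits(csi_mat, "CSIMatrix"))
  linkage <- match.arg(linkage)
  N <- nrow(csi_mat$values)
  if (n_modules < 1 || n_modules > N) stopf("n_modules must be in [1, %d]", N)
  d <- dist(csi_mat$values)
  hc <- hclust(d, method = if (linkage == "ward") "ward.D2" else linkage)
  cut_sized <- function(k) {
    raw <- cutree(hc, k = k)
    sizes <- sort(table(raw), decreasing = TRUE)
    relabel <- setNames(seq_along(sizes), names(sizes))
    setNames(as.integer(relabel[as.character(raw)]), names(raw))
  }
  module <- cut_sized(n_modules)
  dm <- as.matrix(d)
  sil <- vapply(seq(2L, max(2L, min(N - 1L, 10L))), function(k) {
    cl <- cutree(hc, k = k)
    mean(vapply(seq_len(N), function(i) {
      own <- cl == cl[i]; own[i] <- FALSE
      a <- if (any(own)) mean(dm[i, own]) else 0
      b <- min(vapply(setdiff(unique(cl), cl[i]),
                      function(o) mean(dm[i, cl == o]), numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1)))
  }, numeric(1))
  names(sil) <- seq(2L, max(2L, min(N - 1L, 10L)))
  structure(list(module = module,
                 members = split(names(module), module),
                 hclust = hc, n_modules = as.integer(n_modules),
                 silhouette = sil),
            class = "RegulonModuleSet")
}

#' @method print RegulonModuleSet
#' @export
print.RegulonModuleSet <- function(x, ...) {
  cat(sprintf("RegulonModuleSet: %d regulons in %d modules (sizes %s)\n",
              length(x$module), x$n_modules,
              paste(lengths(x$members), collapse = ", ")))
  if (length(x$silhouette)) {
    best <- names(x$silhouette)[which.max(x$silhouette)]
    cat(sprintf("  silhouette suggests %s modules (width %.3f)\n", best,
                max(x$silhouette)))
  }
  invisible(x)
}

#' Module activity per cell type
#'
#' `score(M, t)` is the mean regulon activity over all cells of type `t`
#' and all regulons in module `M`; the top-ranked cell type per module is
#' reported.
#'
#' @param modules a `RegulonModuleSet`.
#' @param ras a `RegulonActivityMatrix` whose columns the modules partition.
#' @param celltypes cell-type label per cell (aligned or named by cell id).
#' @return list with `scores` (modules x cell types) and `top_type` (named
#'   character, per module).
#' @export
module_activity <- function(modules, ras, celltypes) {
  stopifnot(inherits(modules, "RegulonModuleSet"),
            inherits(ras, "RegulonActivityMatrix"))
  if (!setequal(names(modules$module), colnames(ras$scores))) {
    stopf("modules do not partition the activity-matrix columns")
  }
  if (!is.null(names(celltypes))) celltypes <- celltypes[rownames(ras$scores)]
  types <- sort(unique(celltypes[!is.na(celltypes)]))
  if (anyNA(celltypes)) warnf("cells with missing type dropped")
  mids <- sort(unique(modules$module))
  scores <- matrix(NA_real_, length(mids), length(types),
                   dimnames = list(paste0("M", mids), types))
  for (mi in seq_along(mids)) {
    regs <- names(modules$module)[modules$module == mids[mi]]
    for (t in types) {
      scores[mi, t] <- mean(ras$scores[which(celltypes == t), regs, drop = FALSE])
    }
  }
  top <- colnames(scores)[apply(scores, 1, which.max)]
  names(top) <- rownames(scores)
  list(scores = scores, top_type = top)
}

#' CSI association network edges
#'
#' Undirected edges between regulon pairs with CSI strictly above `cutoff`.
#'
#' @param csi_mat a `CSIMatrix`.
#' @param cutoff CSI cutoff in [0,1] (default 0.7).
#' @return data.frame with `from`, `to`, `csi`.
#' @export
csi_network <- function(csi_mat, cutoff = 0.7) {
  stopifnot(inherits(csi_mat, "CSIMatrix"))
  assert_scalar_number(cutoff, "cutoff", 0, 1)
  v <- csi_mat$values
  idx <- which(upper.tri(v) & v > cutoff, arr.ind = TRUE)
  data.frame(from = rownames(v)[idx[, 1]], to = colnames(v)[idx[, 2]],
             csi = v[idx], stringsAsFactors = FALSE)
}
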