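# Internal helpers shared across modules.

#' @importFrom methods as is
#' @importFrom stats cor cor.test dist hclust cutree kmeans median p.adjust
#'   pnorm ppois quantile rexp rnbinom rnorm runif sd setNames
#'   wilcox.test dnorm uniroot pchisq
#' @importFrom utils head read.delim write.table
NULL

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a per-stage seed from a global seed; keeps results < 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a single finite number", name)
  }
  ok_lo <- if (lower_open) x > lower else x >= lower
  ok_hi <- if (upper_open) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    stopf("'%s' = %g is outside the allowed range %s%g, %g%s", name, x,
          if (lower_open) "(" else "[", lower, upper,
          if (upper_open) ")" else "]")
  }
  invisible(x)
}

# Locale-independent ordering of character ids (C collation via radix sort).
order_ids <- function(ids) order(ids, method = "radix")

# Rank position (1 = first in C-locale sort) of each id; used as the
# deterministic tie-break everywhere expression values tie.
id_tiebreak <- function(ids) {
  r <- integer(length(ids))
  r[order_ids(ids)] <- seq_along(ids)
  r
}

# Dense matrix view of a (possibly sparse) genes x cells matrix.
as_dense <- function(m) {
  if (is(m, "Matrix")) as.matrix(m) else m
}

# Euclidean k-nearest-neighbour indices of `query` rows among `ref` rows.
# Returns an n_query x k matrix of row indices into `ref`.
knn_index <- function(ref, query, k, exclude_self = FALSE) {
  k <- as.integer(k)
  rn2 <- rowSums(ref^2)
  idx <- matrix(0L, nrow(query), k)
  step <- max(1L, as.integer(2e7 / max(1L, nrow(ref))))
  for (start in seq(1L, nrow(query), by = step)) {
    rows <- start:min(nrow(query), start + step - 1L)
    d2 <- outer(rowSums(query[rows, , drop = FALSE]^2), rn2, "+") -
      2 * tcrossprod(query[rows, , drop = FALSE], ref)
    for (i in seq_along(rows)) {
      di <- d2[i, ]
      if (exclude_self) di[rows[i]] <- Inf
      idx[rows[i], ] <- order(di)[seq_len(k)]
    }
  }
  idx
}
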