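test_that("normalization follows the stated formula and preserves ranks", {
  mat <- matrix(0, 3, 2)
  mat[1, 1] <- 500; mat[2, 1] <- 4500
  mat[1, 2] <- 3; mat[3, 2] <- 7
  m <- toy_cells(mat)
  nm <- normalize_log(m)
  v <- as.matrix(nm$values)
  expect_equal(v[1, 1], log2(1 + 500 / 5000 * 1e4))   # ~9.9673
  expect_equal(v[1, 1], 9.9673, tolerance = 1e-4)
  expect_equal(v[3, 1], 0)
  # scaling a cell's counts leaves its normalized vector unchanged
  m2 <- toy_cells(cbind(mat[, 1], mat[, 1] * 3))
  v2 <- as.matrix(normalize_log(m2)$values)
  expect_equal(v2[, 1], v2[, 2])
  # rank preservation
  set.seed(1)
  big <- toy_cells(matrix(rpois(300, 3), 30, 10))
  nb <- as.matrix(normalize_log(big)$values)
  for (j in 1:10) expect_equal(rank(nb[, j]), rank(as.matrix(big$counts)[, j]))
  # zero-total cells are an error
  zero <- toy_cells(cbind(mat[, 1], 0))
  expect_error(normalize_log(zero), "zero total UMIs")
})

test_that("PCA captures rank-1 structure, reconstructs exactly, and is sign-stable", {
  set.seed(3)
  u <- rnorm(40); w <- rnorm(25)
  v <- abs(outer(u, w)) + 0.01
  dimnames(v) <- list(sprintf("g%02d", 1:40), sprintf("c%02d", 1:25))
  r1 <- normalized_matrix(v, "test")
  emb <- pca_embed(r1, n_pcs = 5)
  expect_gt(emb$sdev[1]^2 / sum(emb$sdev^2), 1 - 1e-6)

  x <- matrix(abs(rnorm(30 * 20)), 30, 20,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("c%02d", 1:20)))
  nm <- normalized_matrix(x, "test")
  full <- pca_embed(nm, n_pcs = 20)
  xs <- (x - rowMeans(x)) / apply(x, 1, sd)
  expect_lt(max(abs(t(full$coords %*% t(full$loadings)) - xs)), 1e-8)

  e1 <- pca_embed(nm, n_pcs = 5); e2 <- pca_embed(nm, n_pcs = 5)
  expect_identical(e1$coords, e2$coords)
  expect_error(pca_embed(nm, n_pcs = 25), "n_pcs")
})

test_that("graph clustering recovers planted blobs and is order-invariant", {
  set.seed(11)
  blob <- rbind(matrix(rnorm(100 * 2), ncol = 2),
                matrix(rnorm(100 * 2, mean = 10), ncol = 2))
  rownames(blob) <- sprintf("c%03d", 1:200)
  truth <- rep(1:2, each = 100)
  cl <- cluster_graph(blob, k_graph = 20, resolution = 0.6, seed = 2)
  expect_equal(mclust::adjustedRandIndex(cl, truth), 1.0)

  perm <- sample(200)
  cl_p <- cluster_graph(blob[perm, ], k_graph = 20, resolution = 0.6, seed = 2)
  expect_identical(unname(cl_p[rownames(blob)]), unname(cl))

  # resolution -> 0 on a connected graph collapses to one community
  one_cloud <- matrix(rnorm(150 * 2), ncol = 2,
                      dimnames = list(sprintf("d%03d", 1:150), NULL))
  cl0 <- cluster_graph(one_cloud, k_graph = 20, resolution = 1e-4, seed = 2)
  expect_equal(length(unique(cl0)), 1L)
  expect_error(cluster_graph(blob, k_graph = 1), "k_graph")
})

test_that("marker detection honours min.pct and finds perfect separators", {
  set.seed(5)
  n <- 60
  x <- matrix(abs(rnorm(40 * n, 1)), 40, n,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("c%03d", 1:n)))
  cl <- setNames(rep(0:1, each = n / 2), colnames(x))
  x["g01", ] <- ifelse(cl == 0, 5, 0)               # perfect separator of 0
  x["g02", ] <- 0; x["g02", cl == 1][1:3] <- 2      # 10% in-cluster, 0% out
  nm <- normalized_matrix(x, "test")
  mk <- find_markers(nm, cl, min_pct = 0.25)
  top0 <- mk[mk$cluster == 0, ][1, ]
  expect_equal(top0$gene, "g01")
  expect_false("g02" %in% mk$gene)
  expect_true(all(mk$p_adj >= mk$p))
})

test_that("null labels produce no significant markers", {
  set.seed(8)
  x <- matrix(abs(rnorm(30 * 40, 1)), 30, 40,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("c%03d", 1:40)))
  nm <- normalized_matrix(x, "test")
  hits <- vapply(1:20, function(i) {
    cl <- setNames(sample(rep(0:1, each = 20)), colnames(x))
    any(find_markers(nm, cl)$p_adj < 0.05)
  }, logical(1))
  expect_gte(mean(!hits), 0.95)
})

test_that("signature annotation labels dominant lineages and breaks ties alphabetically", {
  x <- matrix(0.1, 6, 20,
              dimnames = list(c("CD14", "LYZ", "CD3D", "CD3E", "o1", "o2"),
                              sprintf("c%02d", 1:20)))
  cl <- setNames(rep(0:1, each = 10), colnames(x))
  x[c("CD14", "LYZ"), cl == 0] <- 5
  x[c("CD3D", "CD3E"), cl == 1] <- 5
  nm <- normalized_matrix(x, "test")
  sig <- list(myeloid = c("CD14", "LYZ"), T = c("CD3D", "CD3E"))
  lab <- annotate_by_markers(sig, nm, cl)
  expect_equal(unname(lab[c("0", "1")]), c("myeloid", "T"))
  # tie: identical signatures -> alphabetical winner with warning
  sig2 <- list(beta = "CD14", alpha = "CD14")
  expect_warning(expect_warning(lab2 <- annotate_by_markers(sig2, nm, cl), "tie"),
                 "tie")   # one tie warning per cluster
  expect_true(all(lab2 == "alpha"))
  expect_warning(annotate_by_markers(c(sig, list(ghost = "NOPE")), nm, cl),
                 "unassignable")
})

test_that("fractions sum to one per sample and the <10-cell filter flags rows", {
  meta <- data.frame(
    sample_id = c(rep("s1", 100), rep("s2", 40)),
    celltype = c(rep("myeloid", 19), rep("T", 81), rep("myeloid", 9), rep("T", 31)),
    response = c(rep("responder", 100), rep("nonresponder", 40)))
  m <- toy_cells(matrix(1, 3, 140), meta = meta)
  fr <- cell_fractions(m)
  expect_equal(fr$fraction[fr$sample_id == "s1" & fr$lineage == "myeloid"], 0.19)
  agg <- tapply(fr$fraction, fr$sample_id, sum)
  expect_true(all(abs(agg - 1) < 1e-12))
  expect_false(fr$kept[fr$sample_id == "s2" & fr$lineage == "myeloid"])
  one <- toy_cells(matrix(1, 2, 12),
                   meta = data.frame(sample_id = rep("s", 12), celltype = "T",
                                     response = "responder"))
  expect_equal(cell_fractions(one)$fraction, 1.0)
})
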