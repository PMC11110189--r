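test_that("the recovery-curve score matches hand-enumerated cases", {
  # 10 genes, window T = 5, targets at ranks 1 and 3 -> 8/9
  expr <- 10:1
  m <- toy_cells(matrix(expr, ncol = 1), gene_ids = sprintf("g%02d", 1:10))
  reg <- regulon("R", c("g01", "g03"))
  s <- aucell(m, reg, threshold_fraction = 0.5)$scores[1, 1]
  expect_equal(s, 8 / 9)
  # all targets below the window -> 0
  reg_low <- regulon("L", c("g09", "g10"))
  expect_equal(aucell(m, reg_low, threshold_fraction = 0.5)$scores[1, 1], 0)
  # targets occupy the top ranks -> 1
  reg_top <- regulon("T", c("g01", "g02"))
  expect_equal(aucell(m, reg_top, threshold_fraction = 0.5)$scores[1, 1], 1)
  expect_error(aucell(m, list()), "at least one regulon")
})

test_that("scores equal the brute-force oracle exactly on random tied instances", {
  set.seed(42)
  gene_ids <- sprintf("g%02d", 1:30)
  for (i in 1:250) {
    expr <- sample(0:5, 30, replace = TRUE)        # heavy ties
    targets <- sample(gene_ids, sample(1:10, 1))
    frac <- sample(c(0.1, 0.2, 0.5, 1), 1)
    m <- toy_cells(matrix(expr, ncol = 1), gene_ids = gene_ids)
    got <- aucell(m, regulon("R", targets), threshold_fraction = frac)$scores[1, 1]
    expect_identical(got, aucell_oracle(expr, gene_ids, targets, frac))
  }
})

test_that("scores are invariant under strictly monotone per-cell transforms", {
  set.seed(7)
  mat <- matrix(rpois(50 * 20, 2), 50, 20)
  m <- toy_cells(mat)
  reg <- regulon("R", sample(m$gene_ids, 8))
  s1 <- aucell(m, reg)$scores
  v <- exp(as.matrix(m$counts) / 3)      # strictly monotone
  dimnames(v) <- dimnames(m$counts)
  s2 <- aucell(normalized_matrix(v, "mono"), reg)$scores
  expect_equal(s1, s2)
})

test_that("binarization thresholds separate bimodal scores and handle degenerate columns", {
  set.seed(9)
  scores <- cbind(bimodal = c(rnorm(150, 0.2, 0.05), rnorm(150, 0.8, 0.05)),
                  flat = rep(0.4, 300))
  rownames(scores) <- sprintf("c%03d", 1:300)
  ras <- structure(list(scores = scores, threshold_fraction = 0.05,
                        thresholds = NULL, binary = NULL),
                   class = "RegulonActivityMatrix")
  expect_warning(b <- binarize(ras, "gmm2"), "constant")
  expect_gt(b$thresholds[["bimodal"]], 0.3)
  expect_lt(b$thresholds[["bimodal"]], 0.7)
  expect_false(any(b$binary[, "flat"]))
  expect_equal(unname(colMeans(b$binary)[1]), 0.5, tolerance = 0.05)

  f <- suppressWarnings(binarize(ras, "fixed", fixed_value = 0.5))
  expect_identical(unname(f$binary[c(1, 300), "bimodal"]), c(FALSE, TRUE))
  o <- suppressWarnings(binarize(ras, "otsu"))
  expect_gt(o$thresholds[["bimodal"]], 0.3)
  expect_lt(o$thresholds[["bimodal"]], 0.7)
})

test_that("RSS is 1 for a perfectly type-restricted regulon and 0 for disjoint support", {
  types <- rep(c("myeloid", "T"), each = 10)
  names(types) <- sprintf("c%02d", 1:20)
  scores <- cbind(specific = ifelse(types == "myeloid", 0.5, 0),
                  anti = ifelse(types == "myeloid", 0, 0.3))
  rownames(scores) <- names(types)
  ras <- structure(list(scores = scores, threshold_fraction = 0.05),
                   class = "RegulonActivityMatrix")
  rss <- regulon_specificity(ras, types)
  get <- function(r, t) rss$rss[rss$regulon == r & rss$celltype == t]
  expect_equal(get("specific", "myeloid"), 1)
  expect_equal(get("specific", "T"), 0)
  expect_equal(get("anti", "myeloid"), 0)
  expect_true(all(rss$rss >= 0 & rss$rss <= 1))
  expect_error(regulon_specificity(ras, rep("one", 20)), "2 cell types")
})

test_that("permuting type labels degrades the RSS of a specific regulon", {
  set.seed(15)
  types <- rep(c("myeloid", "T", "B"), each = 20)
  names(types) <- sprintf("c%02d", 1:60)
  scores <- cbind(spec = ifelse(types == "myeloid", runif(60, 0.4, 0.6), runif(60, 0, 0.05)))
  rownames(scores) <- names(types)
  ras <- structure(list(scores = scores, threshold_fraction = 0.05),
                   class = "RegulonActivityMatrix")
  base <- regulon_specificity(ras, types)
  base_rss <- base$rss[base$celltype == "myeloid"]
  perm_rss <- vapply(1:20, function(i) {
    pt <- setNames(sample(types), names(types))
    r <- regulon_specificity(ras, pt)
    r$rss[r$celltype == "myeloid"]
  }, numeric(1))
  expect_gt(base_rss, mean(perm_rss))
  expect_true(all(perm_rss < base_rss))
})

test_that("the planted myeloid regulon ranks first among decoys on synthetic data", {
  cfg <- small_config(seed = 31)
  m <- simulate_cells(cfg)
  qc <- qc_filter(m, qc_thresholds(min_genes = 200))
  meta <- qc$filtered$cell_meta
  set.seed(1)
  decoys <- lapply(1:5, function(i) {
    regulon(paste0("DECOY", i), sample(qc$filtered$gene_ids, 23))
  })
  regs <- c(list(PPARG = pparg_regulon()), setNames(decoys, paste0("DECOY", 1:5)))
  ras <- aucell(qc$filtered, regs)
  rss <- regulon_specificity(ras, setNames(meta$celltype, meta$cell_id))
  myl <- rss[rss$celltype == "myeloid", ]
  expect_equal(myl$regulon[myl$rank == 1], "PPARG")
})
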