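# Shared fixture: one simulated cohort, gated myeloid cells, and an atlas.
# The gate's single-gene rank indicator needs the full-size gene universe
# (top-5% window of 2000 genes); compact universes squeeze the window and
# are exercised elsewhere.
fix <- local({
  cfg <- synthetic_config(seed = 41, n_cells_per_sample = 300L)
  m <- simulate_cells(cfg)
  qc <- qc_filter(m)
  nm <- normalize_log(qc$filtered)
  gate <- gate_myeloid(nm)
  keep <- match(gate$cell_ids, nm$cell_ids)
  myeloid_nm <- normalized_matrix(nm$values[, keep, drop = FALSE], nm$transform_tag)
  atlas <- build_reference(myeloid_nm, pparg_regulon(), n_clusters = 6, seed = 3)
  list(m = m, qc = qc, nm = nm, gate = gate,
       myeloid_nm = myeloid_nm, atlas = atlas)
})

test_that("marker gating recovers planted myeloid cells (F1 >= 0.95)", {
  meta <- fix$qc$filtered$cell_meta
  truth <- meta$celltype == "myeloid" & !meta$is_doublet
  called <- meta$cell_id %in% fix$gate$cell_ids
  f1 <- 2 * sum(truth & called) / (sum(truth) + sum(called))
  expect_gte(f1, 0.95)
  # zero positive-marker expression fails for any positive threshold
  zero_cd14 <- as.matrix(fix$nm$values[, 1, drop = FALSE])
  zero_cd14["CD14", ] <- 0
  nm0 <- normalized_matrix(zero_cd14, "test")
  g0 <- gate_myeloid(nm0, gate_spec(pos_threshold = 0))
  expect_equal(g0$scores$pos_score, 0)
  expect_false(g0$scores$pass)
})

test_that("gating validates marker availability", {
  nm_small <- normalized_matrix(
    matrix(1:4, 2, 2, dimnames = list(c("X1", "X2"), c("c1", "c2"))), "t")
  expect_error(gate_myeloid(nm_small), "no positive marker")
  nm_nofc <- normalized_matrix(
    matrix(1:4, 2, 2, dimnames = list(c("CD14", "X2"), c("c1", "c2"))), "t")
  expect_warning(gate_myeloid(nm_nofc), "negative marker")
  expect_error(gate_spec(positive_markers = "CD14", negative_markers = "CD14"),
               "disjoint")
})

test_that("the atlas flags exactly the clusters with median activity above the cutoff", {
  a <- fix$atlas
  expect_identical(a$response_associated_clusters,
                   which(a$median_activity > a$high_score_cutoff))
  expect_gt(length(a$response_associated_clusters), 0)
  expect_lt(length(a$response_associated_clusters), a$n_clusters)
  # deterministic given data + seed
  a2 <- build_reference(fix$myeloid_nm, pparg_regulon(), n_clusters = 6, seed = 3)
  expect_identical(a2$labels, a$labels)
  expect_identical(a2$median_activity, a$median_activity)
  expect_error(build_reference(fix$myeloid_nm, pparg_regulon(), n_clusters = 1),
               "n_clusters")
})

test_that("self-mapping at k = 1 reproduces every reference label; fractions sum to 1", {
  mapped <- map_query(fix$atlas, fix$myeloid_nm, k_transfer = 1)
  expect_identical(mapped$cluster, unname(fix$atlas$labels[mapped$cell_id]))
  expect_true(all(mapped$confidence == 1))
  frac <- table(mapped$cluster) / nrow(mapped)
  expect_equal(sum(frac), 1, tolerance = 1e-12)
})

test_that("queries with insufficient gene coverage are rejected", {
  v <- matrix(1, 3, 2, dimnames = list(c("Z1", "Z2", "Z3"), c("q1", "q2")))
  expect_error(map_query(fix$atlas, normalized_matrix(v, "t")), "coverage|atlas genes")
})

test_that("atlas serialization round-trips through TSV + JSON", {
  dir <- withr::local_tempdir()
  write_reference(fix$atlas, dir)
  a2 <- read_reference(dir)
  expect_equal(a2$gene_means, fix$atlas$gene_means, tolerance = 1e-6)
  expect_identical(a2$labels, fix$atlas$labels)
  expect_identical(a2$response_associated_clusters,
                   fix$atlas$response_associated_clusters)
  expect_equal(a2$regulon$targets, fix$atlas$regulon$targets)
  mapped1 <- map_query(fix$atlas, fix$myeloid_nm, k_transfer = 5)
  mapped2 <- map_query(a2, fix$myeloid_nm, k_transfer = 5)
  expect_gt(mean(mapped1$cluster == mapped2$cluster), 0.99)
})

test_that("the end-to-end report separates responder from nonresponder queries", {
  meta <- fix$m$cell_meta
  resp <- subset_cells(fix$m, which(meta$response == "responder"))
  nonresp <- subset_cells(fix$m, which(meta$response == "nonresponder"))
  r1 <- pparg_report(resp, fix$atlas)
  r0 <- pparg_report(nonresp, fix$atlas)
  expect_gt(r1$n_myeloid, 0)
  expect_equal(sum(r1$cluster_fractions), 1, tolerance = 1e-12)
  expect_gt(r1$fraction_in_response_clusters, r0$fraction_in_response_clusters)
  expect_gt(r1$activity_median, r0$activity_median)
  # determinism
  r1b <- pparg_report(resp, fix$atlas)
  expect_identical(r1b$cluster_fractions, r1$cluster_fractions)
})

test_that("a query without myeloid cells yields a flagged, not failing, report", {
  meta <- fix$m$cell_meta
  tonly <- subset_cells(fix$m, which(meta$celltype == "T" & !meta$is_doublet))
  rep0 <- pparg_report(tonly, fix$atlas)
  expect_equal(rep0$n_myeloid, 0)
  expect_true(is.na(rep0$fraction_in_response_clusters))
  expect_true(all(is.na(rep0$cluster_fractions)))
})
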