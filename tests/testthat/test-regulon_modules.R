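test_that("the worked 4-regulon example gives CSI(A,B) = 1/2 and boundary pairs hit 0/1", {
  pcc <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  pcc["A", "B"] <- pcc["B", "A"] <- 0.9
  pcc["A", "C"] <- pcc["C", "A"] <- 0.5
  pcc["B", "C"] <- pcc["C", "B"] <- 0.4
  pcc["A", "D"] <- pcc["D", "A"] <- 0.95
  pcc["B", "D"] <- pcc["D", "B"] <- 0.3
  pcc["C", "D"] <- pcc["D", "C"] <- 0.1
  vals <- myeloregulon:::csi_from_pcc(pcc)
  expect_equal(vals["A", "B"], 0.5)   # C qualifies, D does not
  # a pair above every other correlation involving either member -> CSI 1
  expect_equal(vals["A", "D"], 1)     # B: .9<.95 & .3<.95; C: .5<.95 & .1<.95
  # a pair below every other correlation involving either member -> CSI 0
  expect_equal(vals["C", "D"], 0)
  # network edges use a strict cutoff
  cm <- structure(list(values = vals, pcc = pcc), class = "CSIMatrix")
  edges <- csi_network(cm, cutoff = 0.4)
  expect_true(any(edges$from == "A" & edges$to == "B"))
  expect_equal(nrow(csi_network(cm, cutoff = 1.0)), 0)
})

test_that("CSI equals the double-loop oracle exactly on random activity matrices", {
  set.seed(77)
  for (i in 1:40) {
    scores <- matrix(runif(50 * 10), 50, 10,
                     dimnames = list(sprintf("c%02d", 1:50), sprintf("R%02d", 1:10)))
    got <- csi(scores)$values
    expect_equal(got, csi_oracle(scores), tolerance = 1e-12)
    expect_identical(got, t(got))
    expect_true(all(got >= 0 & got <= 1))
    expect_true(all(diag(got) == 1))
  }
})

test_that("CSI is invariant to regulon order and rejects constant columns", {
  set.seed(5)
  scores <- matrix(runif(40 * 6), 40, 6,
                   dimnames = list(sprintf("c%02d", 1:40), sprintf("R%d", 1:6)))
  c1 <- csi(scores)$values
  perm <- c(4, 2, 6, 1, 3, 5)
  c2 <- csi(scores[, perm])$values
  expect_equal(c2[colnames(c1), colnames(c1)], c1)
  scores[, 2] <- 0.5
  expect_error(csi(scores), "constant activity.*R2")
  expect_error(csi(scores[, 1:2]), "at least 3")
})

test_that("module detection recovers planted co-active groups", {
  set.seed(12)
  n <- 200
  drivers <- matrix(rnorm(n * 3), n, 3)
  scores <- sapply(1:12, function(r) {
    g <- (r - 1) %/% 4 + 1
    pmax(0, drivers[, g] + rnorm(n, sd = 0.3))
  })
  dimnames(scores) <- list(sprintf("c%03d", 1:n), sprintf("R%02d", 1:12))
  cm <- csi(scores)
  mod <- detect_modules(cm, n_modules = 3)
  truth <- rep(1:3, each = 4)
  expect_equal(mclust::adjustedRandIndex(mod$module[colnames(scores)], truth), 1.0)
  # full cut -> singletons; invalid cut -> error
  modN <- detect_modules(cm, n_modules = 12)
  expect_true(all(lengths(modN$members) == 1))
  expect_error(detect_modules(cm, n_modules = 13), "n_modules")
})

test_that("block-diagonal CSI with two perfect blocks splits into the blocks", {
  v <- matrix(0, 6, 6, dimnames = list(sprintf("R%d", 1:6), sprintf("R%d", 1:6)))
  v[1:3, 1:3] <- 0.9; v[4:6, 4:6] <- 0.9; diag(v) <- 1
  cm <- structure(list(values = v, pcc = v), class = "CSIMatrix")
  mod <- detect_modules(cm, n_modules = 2)
  expect_equal(length(unique(mod$module[1:3])), 1L)
  expect_equal(length(unique(mod$module[4:6])), 1L)
  expect_false(mod$module[1] == mod$module[4])
})

test_that("module activity averages members per type and finds the top type", {
  types <- setNames(rep(c("myeloid", "T"), each = 5), sprintf("c%02d", 1:10))
  scores <- cbind(R1 = c(rep(0.8, 5), rep(0.1, 5)),
                  R2 = c(rep(0.6, 5), rep(0.2, 5)),
                  R3 = rep(0.3, 10))
  rownames(scores) <- names(types)
  ras <- structure(list(scores = scores, threshold_fraction = 0.05),
                   class = "RegulonActivityMatrix")
  cmv <- matrix(0.2, 3, 3, dimnames = list(colnames(scores), colnames(scores)))
  cmv[1, 2] <- cmv[2, 1] <- 0.9; diag(cmv) <- 1
  cm <- structure(list(values = cmv, pcc = cmv), class = "CSIMatrix")
  mod <- detect_modules(cm, n_modules = 2)
  act <- module_activity(mod, ras, types)
  m12 <- paste0("M", mod$module[["R1"]])
  expect_equal(act$scores[m12, "myeloid"], 0.7)     # mean of R1, R2 in myeloid
  expect_equal(act$top_type[[m12]], "myeloid")
  # a single-regulon module scores as that regulon's mean
  m3 <- paste0("M", mod$module[["R3"]])
  expect_equal(unname(act$scores[m3, ]), c(0.3, 0.3), ignore_attr = TRUE)
})
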