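test_that("one-sided Wilcoxon matches exhaustive enumeration on small instances", {
  r <- wilcoxon_one_sided(c(5, 6, 7), c(1, 2, 3), "greater")
  expect_equal(r$p, 1 / 20)
  expect_equal(r$method, "exact")
  set.seed(4)
  for (i in 1:25) {
    x <- sample(1:100, 5); y <- setdiff(sample(1:100, 8), x)[1:5]
    got <- wilcoxon_one_sided(x, y, "greater")
    expect_equal(got$p, wilcoxon_enum_oracle(x, y, "greater"), tolerance = 1e-12)
  }
  same <- wilcoxon_one_sided(c(1, 2, 3), c(1, 2, 3), "greater")
  expect_gte(same$p, 0.5)
  expect_error(wilcoxon_one_sided(numeric(0), 1), "non-empty")
})

test_that("normal approximation tracks the exact test on small tie-free instances", {
  set.seed(6)
  worst <- 0
  for (i in 1:60) {
    x <- sample(seq(1, 1000), 5); y <- setdiff(sample(seq(1, 1000), 10), x)[1:5]
    exact <- wilcoxon_enum_oracle(x, y, "greater")
    approx <- suppressWarnings(
      wilcox.test(x, y, alternative = "greater", exact = FALSE,
                  correct = TRUE)$p.value)
    worst <- max(worst, abs(exact - approx))
  }
  expect_lt(worst, 0.02)
})

test_that("BH adjustment matches hand computation and is monotone, bounded", {
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(2)
  p <- runif(50)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p) && all(adj <= 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Spearman handles monotone relations and matches the permutation oracle", {
  x <- c(1, 3, 5, 9, 12)
  expect_equal(spearman(x, x^3)$rho, 1)
  expect_equal(spearman(x, -x + 100)$rho, -1)
  set.seed(10)
  for (i in 1:10) {
    xs <- sample(1:50, 5); ys <- sample(1:50, 5)
    got <- spearman(xs, ys)
    # exhaustive permutation p for n = 5
    rho_obs <- cor(rank(xs), rank(ys))
    perms <- combinat_perms(5)
    rhos <- apply(perms, 1, function(pm) cor(rank(xs), rank(ys[pm])))
    p_exact <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)
    expect_equal(got$p, p_exact, tolerance = 1e-10)
  }
  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("median split assigns ties to high and rejects degenerate input", {
  s <- median_split(c(1, 2, 3, 4))
  expect_equal(s$group, c("low", "low", "high", "high"))
  s2 <- median_split(c(1, 2, 2, 3))
  expect_equal(s2$group, c("low", "high", "high", "high"))
  expect_error(median_split(rep(2, 4)), "identical")
})

test_that("KM and log-rank behave on identical groups, no events, and a hand-computed instance", {
  rec <- data.frame(time = rep(c(2, 4, 6), 2), event = rep(c(1, 1, 0), 2),
                    group = rep(c("high", "low"), each = 3))
  r <- km_logrank(rec)
  expect_equal(r$chisq, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-12)

  none <- data.frame(time = 1:6, event = 0, group = rep(c("high", "low"), 3))
  expect_warning(r0 <- km_logrank(none), "no events")
  expect_true(all(r0$curves$survival == 1))
  expect_equal(r0$p, 1)

  # toy instance: A = (1e, 2e, 3c), B = (4e, 5e, 6c); hand O-E computation
  toy <- data.frame(time = 1:6, event = c(1, 1, 0, 1, 1, 0),
                    group = rep(c("A", "B"), each = 3))
  # event times 1,2,4,5; observed A = 2; expected A = 3/6 + 2/5 + 0 + 0 = 0.9
  # variances: t=1: 3*3*5*1/(36*5)=.25; t=2: 2*3*4*1/(25*4)=.24;
  # t=4: 0; t=5: 0 -> V = .49; chi2 = (2-0.9)^2/.49
  rt <- km_logrank(toy)
  expect_equal(rt$chisq, (2 - 0.9)^2 / 0.49, tolerance = 1e-10)
  expect_equal(rt$p, pchisq((2 - 0.9)^2 / 0.49, 1, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("log-rank p is uniform under label permutation", {
  set.seed(33)
  times <- rexp(40, 0.1); ev <- rbinom(40, 1, 0.7)
  ps <- vapply(1:400, function(i) {
    g <- sample(rep(c("high", "low"), each = 20))
    km_logrank(data.frame(time = times, event = ev, group = g))$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
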