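test_that("template projection is a nearest-template rule with ties to 1", {
  tmpl <- rbind(rep(0, 6), rep(1, 6))
  expect_equal(projectToTemplates(tmpl[1, ], tmpl), 1L)
  expect_equal(projectToTemplates(tmpl[2, ], tmpl), 2L)
  # exact equidistance goes to biotype 1
  expect_equal(projectToTemplates(rep(0.5, 6), tmpl), 1L)
  expect_error(projectToTemplates(rep(0, 4), tmpl), "projection error")
})

test_that("covariate-adjusted t equals the pooled t-test without covariates", {
  res <- adjustedTwoSampleT(c(1, 2, 3, 4, 5, 6),
                            factor(rep(c("a", "b"), each = 3)))
  oracle <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(res$t, unname(oracle$statistic))
  expect_equal(res$p, oracle$p.value)
  # identical group means
  res0 <- adjustedTwoSampleT(c(1, 2, 1, 2), factor(c("a", "a", "b", "b")))
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  # 50 random instances against t.test
  for (s in 1:50) {
    set.seed(s)
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    v <- c(rnorm(n1), rnorm(n2, 0.5))
    gfac <- factor(rep(c("g1", "g2"), c(n1, n2)))
    got <- adjustedTwoSampleT(v, gfac)
    ora <- t.test(v[gfac == "g1"], v[gfac == "g2"], var.equal = TRUE)
    expect_equal(got$t, unname(ora$statistic), tolerance = 1e-8)
    expect_equal(got$p, ora$p.value, tolerance = 1e-8)
  }
})

test_that("a planted confound is removed by covariate adjustment", {
  set.seed(12)
  n <- 60
  gfac <- factor(rep(c("a", "b"), each = n / 2))
  z <- rnorm(n) + 2 * (gfac == "a")      # confound differs by group
  v <- 3 * z + rnorm(n, 0, 0.5)          # outcome driven only by z
  raw <- adjustedTwoSampleT(v, gfac)
  adj <- adjustedTwoSampleT(v, gfac, covariates = cbind(z))
  expect_lt(raw$p, 0.01)
  expect_gt(adj$p, raw$p * 100)
  expect_error(adjustedTwoSampleT(v, gfac, covariates = cbind(z, 2 * z)),
               "collinear")
})

test_that("Cohen's d uses the df-weighted pooled standard deviation", {
  set.seed(3)
  x <- rnorm(50, 1, 1); y <- rnorm(50, 0, 1)
  d <- cohensD(c(x, y), factor(rep(c("x", "y"), each = 50)))
  expect_equal(d, (mean(x) - mean(y)) /
                 sqrt((49 * var(x) + 49 * var(y)) / 98))
  expect_gt(d, 0.5)
  expect_equal(cohensD(c(1, 2, 1, 2), factor(c("a", "a", "b", "b"))), 0)
  # hand-computed 4 + 4 sample
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 6)
  sp <- sqrt((3 * var(a) + 3 * var(b)) / 6)
  expect_equal(cohensD(c(a, b), factor(rep(c("a", "b"), each = 4))),
               (mean(a) - mean(b)) / sp)
  expect_error(cohensD(rep(1, 6), factor(rep(c("a", "b"), each = 3))),
               "zero pooled SD")
})

test_that("FDR adjustment is step-up Benjamini-Hochberg", {
  expect_equal(fdrAdjust(0.37), 0.37)
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(fdrAdjust(rep(0.2, 5)), rep(0.2, 5))
  bhOracle <- function(p) {
    m <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(m / (m:1) * p[o]))[ro]
  }
  for (s in 1:100) {
    set.seed(s)
    p <- runif(sample(3:40, 1))
    got <- fdrAdjust(p)
    expect_equal(got, bhOracle(p), tolerance = 1e-12)
    expect_true(all(got >= p))
  }
  expect_error(fdrAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("discriminative edge ranking recovers planted group shifts", {
  set.seed(14)
  n <- 120; C <- 7; d <- C * (C - 1) / 2    # 21 edges
  gfac <- factor(rep(c("b1", "hc"), each = n / 2))
  X <- matrix(rnorm(n * d, 0, 0.1), n)
  planted <- c(2, 5, 9, 13, 20)
  X[gfac == "b1", planted] <- X[gfac == "b1", planted] + 0.5
  top5 <- topDiscriminativeFNC(X, gfac, k = 5)
  expect_setequal(top5$edgeIdx, planted)
  # full ranking equals a brute-force per-edge t oracle
  full <- topDiscriminativeFNC(X, gfac, k = d)
  tOracle <- sapply(1:d, function(e)
    t.test(X[gfac == "b1", e], X[gfac == "hc", e],
           var.equal = TRUE)$statistic)
  expect_equal(full$edgeIdx, order(-abs(tOracle)))
  expect_equal(full$t, unname(tOracle[order(-abs(tOracle))]),
               tolerance = 1e-8)
  expect_warning(topDiscriminativeFNC(X, gfac, k = d + 5), "truncating")
})

test_that("network contributions count unordered block memberships", {
  part <- networkPartition(c(2L, 1L, 1L, 1L, 1L, 2L, 2L))
  # components: SC 1-2, AU 3, SM 4, VI 5, CC 6, DM 7-8, CB 9-10;
  # edges spanning (SC,AU), (SC,AU), (DM,DM), (CC,CB)
  edges <- data.frame(i = c(1, 2, 7, 6), j = c(3, 3, 8, 10))
  ctr <- networkContribution(edges, part)
  expect_equal(ctr["SC", "AU"], 2L)
  expect_equal(ctr["DM", "DM"], 1L)
  expect_equal(ctr["CC", "CB"], 1L)
  expect_equal(sum(ctr[upper.tri(ctr, diag = TRUE)]), 4L)
  expect_true(isSymmetric(ctr))
  # all edges within one network
  e2 <- data.frame(i = c(1, 1), j = c(2, 2))
  ctr2 <- networkContribution(e2, part)
  expect_equal(ctr2["SC", "SC"], 2L)
  expect_equal(sum(ctr2[upper.tri(ctr2, diag = TRUE)]), 2L)
  expect_error(networkContribution(data.frame(i = 1, j = 99), part),
               "partition error")
})

test_that("top-set overlap is an order-stable intersection", {
  expect_length(overlapTopSets(1:100, 1:100), 100)
  expect_length(overlapTopSets(1:50, 51:100), 0)
  expect_length(overlapTopSets(1:100, 75:174), 26)
  expect_identical(overlapTopSets(c(9L, 3L, 7L), c(7L, 9L, 1L)), c(7L, 9L))
})

test_that("cross-cohort consistency is 1 for identical cohorts", {
  set.seed(6)
  ctr <- matrix(rpois(49, 3), 7, 7)
  ctr <- ctr + t(ctr)
  diffV <- rnorm(45)
  out <- crossCohortConsistency(ctr, ctr, diffV, diffV)
  expect_equal(out$r, c(1, 1))
  expect_error(crossCohortConsistency(matrix(2, 7, 7), ctr),
               "zero-variance")
})

test_that("edge-scale correlations flag degenerate pairs and adjust FDR", {
  set.seed(8)
  n <- 200
  x <- rnorm(n)
  scales <- data.frame(copy = x, noise = rnorm(n), const = rep(1, n))
  out <- fncScaleCorrelations(cbind(edge1 = x), scales)
  expect_equal(out$r[out$scale == "copy"], 1)
  expect_identical(out$note[out$scale == "const"], "constant column")
  expect_true(all(out$pFDR >= out$p, na.rm = TRUE))
  # independent columns: |r| <= 0.2 for at least 95% of pairs at n = 200
  E <- matrix(rnorm(n * 10), n)
  S <- matrix(rnorm(n * 10), n)
  nul <- fncScaleCorrelations(E, as.data.frame(S))
  expect_gte(mean(abs(nul$r) <= 0.2), 0.95)
})

test_that("a planted half-variance scale recovers r near sqrt(0.5)", {
  meds <- vapply(1:20, function(s) {
    set.seed(600 + s)
    x <- rnorm(150)
    y <- x + rnorm(150, 0, 1)   # R^2 = 0.5
    cor(x, y)
  }, numeric(1))
  expect_lt(abs(median(meds) - sqrt(0.5)), 0.05)
  # and the package path reports the same correlation
  set.seed(601)
  x <- rnorm(150); y <- x + rnorm(150)
  out <- fncScaleCorrelations(cbind(e = x), data.frame(s = y))
  expect_equal(out$r, cor(x, y))
})
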