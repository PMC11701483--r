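test_that("the cohort generator is deterministic and shape-consistent", {
  spec <- tinySpec(7)
  a <- generateCohort(spec)
  b <- generateCohort(spec)
  expect_identical(fncMatrix(a), fncMatrix(b))
  expect_identical(subjectTable(a), subjectTable(b))
  d <- 20 * 19 / 2
  expect_identical(dim(fncMatrix(a)), c(90L, as.integer(d)))
  st <- subjectTable(a)
  expect_true(all(is.na(st$trueSubtype[st$diagnosis == "control"])))
  expect_true(all(!is.na(st$trueSubtype[st$diagnosis == "patient"])))
  expect_true(all(st$age > 0) && all(st$meanFD >= 0))
  expect_true(all(abs(fncMatrix(a)) < 1))
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohortSpec(subtypeProps = c(0.6, 0.6)), "sum to 1")
  expect_error(cohortSpec(nPatients = 1L), "infeasible|fewer patients")
  expect_error(cohortSpec(noiseSd = 0), "noiseSd")
})

test_that("zero effect size leaves patients and controls exchangeable", {
  co <- generateCohort(tstSpec(5, effectSize = 0))
  st <- subjectTable(co)
  fnc <- fncMatrix(co)
  diffs <- colMeans(fnc[st$diagnosis == "patient", ]) -
    colMeans(fnc[st$diagnosis == "control", ])
  # group mean difference ~ N(0, noiseSd^2 (1/200 + 1/400)) per edge
  expect_lt(mean(abs(diffs)), 0.01)
})

test_that("planted subtype shifts land on affected edges, not elsewhere", {
  spec <- tstSpec(1)
  affected <- which(blockEdgeMask(spec@partition, spec@affectedBlocks[[1]]))
  unaffectedBlocks <- rbind(c(1L, 2L))              # SC-AU: never planted
  unaffected <- which(blockEdgeMask(spec@partition, unaffectedBlocks))
  tAff <- tUnaff <- numeric(20)
  for (r in 1:20) {
    co <- generateCohort(tstSpec(300 + r, nHC = 10L, nPatients = 400L))
    st <- subjectTable(co)
    fnc <- fncMatrix(co)
    pat <- st$diagnosis == "patient"
    g1 <- pat & st$trueSubtype == 1
    g2 <- pat & st$trueSubtype == 2
    tAff[r] <- t.test(fnc[g1, affected[1]], fnc[g2, affected[1]],
                      var.equal = TRUE)$statistic
    tUnaff[r] <- t.test(fnc[g1, unaffected[1]], fnc[g2, unaffected[1]],
                        var.equal = TRUE)$statistic
  }
  expect_true(all(abs(tAff) > abs(tUnaff)))
  # per-edge standardized shift is effectSize, so E|t| ~ 0.8 * sqrt(n/2) ~ 8
  expect_gt(median(abs(tAff)), 4)
  expect_lt(median(abs(tUnaff)), 3)
})

test_that("between-subtype separation grows with effect size", {
  silhouette1 <- function(X, lab) {
    D <- as.matrix(dist(X))
    mean(vapply(seq_along(lab), function(i) {
      a <- mean(D[i, lab == lab[i]][-match(i, which(lab == lab[i]))])
      b <- mean(D[i, lab != lab[i]])
      (b - a) / max(a, b)
    }, numeric(1)))
  }
  meds <- vapply(c(0, 0.4, 0.8), function(eff) {
    median(vapply(1:10, function(s) {
      co <- generateCohort(tinySpec(400 + s, effectSize = eff))
      st <- subjectTable(co)
      pat <- st$diagnosis == "patient"
      silhouette1(fncMatrix(co)[pat, ], st$trueSubtype[pat])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
  expect_lt(abs(meds[1]), 0.05)
})

test_that("time courses reproduce their target correlation structure", {
  # identity target: off-diagonal correlations vanish with T
  tc <- generateTimecourses(diag(1, 8), 5000, seed = 1)
  r <- computeFNC(tc)
  expect_lte(mean(abs(r[upper.tri(r)])), 0.05)
  expect_equal(unname(rowMeans(tc)), rep(0, 8), tolerance = 1e-12)

  # duplicate-component target survives the PSD repair
  target <- diag(1, 3); target[1, 2] <- target[2, 1] <- 1
  tc2 <- generateTimecourses(target, 50, seed = 2)
  expect_gte(computeFNC(tc2)[1, 2], 0.999)

  # r = 0.6 recovered within the Fisher-z sampling bound at T = 10000
  target3 <- diag(1, 2); target3[1, 2] <- target3[2, 1] <- 0.6
  rs <- vapply(1:10, function(s)
    computeFNC(generateTimecourses(target3, 10000, seed = s))[1, 2],
    numeric(1))
  expect_true(all(abs(rs - 0.6) < 0.03))

  expect_error(generateTimecourses(diag(1, 10), 5), "ill-conditioned")
})

test_that("nearest-PSD repair floors eigenvalues and keeps unit diagonal", {
  M <- diag(1, 3); M[1, 2] <- M[2, 1] <- 0.9
  M[1, 3] <- M[3, 1] <- 0.9; M[2, 3] <- M[3, 2] <- -0.9   # not PSD
  R <- nearestPSD(M)
  expect_true(min(eigen(R, symmetric = TRUE)$values) >= 0)
  expect_equal(diag(R), rep(1, 3))
})

test_that("longitudinal trajectories follow the planted recovery model", {
  subj <- data.frame(id = c("a", "b"), biotype = c(1, 2),
                     med = c("MPH", "ATX"))
  # noise-free limit reproduces the deterministic trajectory exactly
  long <- generateLongitudinal(subj, baselineMean = 40, baselineSd = 0,
                               reInterceptSd = 0, reSlopeSd = 0,
                               noiseSd = 0, seed = 1)
  plan <- defaultEffectPlan()
  expect_equal(long$score[long$id == "a"],
               pmax(40 - plan["1", "MPH"] * c(0, 1, 2, 3, 4, 8), 0))
  expect_equal(long$score[long$id == "b"],
               pmax(40 - plan["2", "ATX"] * c(0, 1, 2, 3, 4, 8), 0))
  # scores are floored at zero
  long2 <- generateLongitudinal(subj, baselineMean = 5, baselineSd = 0,
                                reInterceptSd = 0, reSlopeSd = 0,
                                noiseSd = 0, seed = 1)
  expect_true(all(long2$score >= 0))
  expect_true(any(long2$score == 0))

  expect_error(generateLongitudinal(data.frame(id = "a", biotype = NA)),
               "missing biotype")
  expect_error(generateLongitudinal(subj, weeks = c(1, 2)), "baseline")
})
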