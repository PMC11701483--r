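test_that("graph convolution and loss primitives match their oracles", {
  # gcnLayer identity and zero cases
  H <- matrix(rnorm(6), 3)
  expect_equal(gcnLayer(H, diag(3), diag(2)), H)
  expect_equal(gcnLayer(H, diag(3), matrix(0, 2, 2)), matrix(0, 3, 2))
  # 3-node path graph against the dense product oracle
  P <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  Ah <- normalizeAdjacency(P)
  W <- matrix(c(0.3, -0.2, 0.5, 0.1), 2)
  expect_equal(gcnLayer(H, Ah, W, activation = "relu"),
               pmax(Ah %*% H %*% W, 0))
  expect_error(gcnLayer(H, diag(4), W), "dimension")

  # reconstruction loss
  X <- matrix(rnorm(24), 4)
  expect_equal(reconstructionLoss(X, X), 0)
  expect_equal(reconstructionLoss(matrix(0, 2, 2), matrix(1, 2, 2)), 1)
  Y <- matrix(rnorm(24), 4)
  acc <- 0
  for (i in 1:4) for (j in 1:6) acc <- acc + (X[i, j] - Y[i, j])^2
  expect_equal(reconstructionLoss(X, Y), acc / 24)
  expect_error(reconstructionLoss(X, matrix(0, 2, 2)), "dimension")

  # binary cross-entropy
  expect_equal(diagnosticCELoss(rep(0, 5), c(1, 0, 1, 0, 1)), log(2))
  expect_lt(diagnosticCELoss(c(50, -50), c(1, 0)), 1e-10)
  l <- c(0.5, -1.2, 2, 0.1, -0.4); y <- c(1, 0, 1, 0, 1)
  s <- 1 / (1 + exp(-l))
  expect_equal(diagnosticCELoss(l, y),
               -mean(y * log(s) + (1 - y) * log(1 - s)))
  expect_error(diagnosticCELoss(l, y, mask = rep(FALSE, 5)), "empty mask")

  # total loss with the published weights
  cfg <- trainingConfig()
  expect_equal(totalLoss(1, 1, 1, cfg)$total, 0.12)
  expect_equal(totalLoss(0, 0, 0, cfg)$total, 0)
  cfgR <- trainingConfig(gammaRec = 1, gammaCE = 0, gammaCluster = 0)
  expect_equal(totalLoss(0.37, 5, 9, cfgR)$total, 0.37)
  expect_error(trainingConfig(gammaRec = -1), "non-negative")
})

test_that("deep K-means loss interpolates to the hard K-means objective", {
  # every point on a centroid: loss vanishes in the annealed limit and is
  # already tiny at moderate inverse temperature
  Z <- rbind(c(1, 0), c(0, 1), c(1, 0))
  mu <- rbind(c(1, 0), c(0, 1))
  expect_lt(deepKMeansLoss(Z, mu, alpha = 1000), 1e-12)
  expect_lt(deepKMeansLoss(Z, mu, alpha = 3), 0.01)
  # two points at (+-1, 0), one centroid at the origin
  expect_equal(deepKMeansLoss(rbind(c(1, 0), c(-1, 0)),
                              rbind(c(0, 0)), alpha = 2), 1)
  # p = 6, K = 2 at alpha = 1000: nearest-centroid oracle
  set.seed(5)
  Z6 <- matrix(rnorm(12), 6)
  mu2 <- matrix(rnorm(4), 2)
  oracle <- mean(apply(Z6, 1, function(z)
    min(sum((z - mu2[1, ])^2), sum((z - mu2[2, ])^2))))
  expect_equal(deepKMeansLoss(Z6, mu2, alpha = 1000), oracle,
               tolerance = 1e-6)
  expect_error(deepKMeansLoss(Z6[1, , drop = FALSE], mu2, 1), "infeasible")
  expect_error(deepKMeansLoss(Z6 * NA, mu2, 1), "non-finite")
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(8)
  n <- 10; d <- 6; h <- 5; m <- 3; K <- 2
  A <- matrix(runif(n * n) * rbinom(n * n, 1, 0.5), n)
  A <- (A + t(A)) / 2; diag(A) <- 0
  Ahat <- normalizeAdjacency(A)
  X <- matrix(rnorm(n * d), n)
  y <- rbinom(n, 1, 0.5)
  patientIdx <- 1:6
  cfg <- trainingConfig(K = 2L, hiddenDim = h, embeddingDim = m)
  params <- BiotypeGraph:::.initParams(d, h, m)
  params$mu <- matrix(rnorm(K * m), K)
  mask <- rep(TRUE, n)
  AX <- Ahat %*% X
  lossOf <- function(p) {
    BiotypeGraph:::.forwardBackward(p, X, AX, Ahat, y, mask, patientIdx,
                                    mu = p$mu, alpha = 2.5, cfg = cfg,
                                    wantGrads = FALSE)$total
  }
  fb <- BiotypeGraph:::.forwardBackward(params, X, AX, Ahat, y, mask,
                                        patientIdx, mu = params$mu,
                                        alpha = 2.5, cfg = cfg)
  eps <- 1e-6
  for (nm in c("W1", "b2", "W3", "wc", "bc", "mu")) {
    val <- params[[nm]]
    idx <- if (length(val) > 4) sample(length(val), 4) else seq_along(val)
    for (k in idx) {
      pPlus <- params; pPlus[[nm]][k] <- pPlus[[nm]][k] + eps
      pMinus <- params; pMinus[[nm]][k] <- pMinus[[nm]][k] - eps
      fd <- (lossOf(pPlus) - lossOf(pMinus)) / (2 * eps)
      expect_equal(unname(fb$grads[[nm]][k]), fd, tolerance = 1e-4)
    }
  }
})

test_that("farthest-point seeding and nearest-centroid assignment are exact", {
  Z <- rbind(c(0, 0), c(10, 0), c(0.2, 0), c(9.9, 0.1), c(5, 8))
  seeds <- farthestPointSeeds(Z, 3)
  expect_length(unique(seeds), 3)
  # the three chosen points cover the three extremes
  expect_setequal(sort(seeds)[1:2] %in% c(1, 2, 3, 4), c(TRUE, TRUE))
  set.seed(2)
  pts <- matrix(rnorm(12), 6)
  ctr <- matrix(rnorm(4), 2)
  oracle <- apply(pts, 1, function(z)
    which.min(c(sum((z - ctr[1, ])^2), sum((z - ctr[2, ])^2))))
  expect_equal(nearestCentroid(pts, ctr), oracle)
})

test_that("biotype relabeling puts the largest cluster first", {
  co <- generateCohort(tinySpec(6))
  g <- cohortGraph(co)
  pat <- which(patientMask(g))
  n <- length(subjectIds(g))
  emb <- matrix(0, n, 2)
  emb[pat, 1] <- c(rep(0, 45), rep(10, 15))   # 45 vs 15 planted split
  cfg <- tinyConfig(1)
  model <- new("BiotypeModel", params = list(), embeddings = emb,
               centroids = rbind(c(10, 0), c(0, 0)),
               assignments = setNames(rep(1L, length(pat)),
                                      subjectIds(g)[pat]),
               templates = matrix(0, 0, 0), config = cfg,
               lossHistory = data.frame(),
               ids = subjectIds(g), patientMask = patientMask(g))
  out <- assignBiotypes(model, g)
  sizes <- table(biotypes(out))
  expect_equal(unname(sizes["1"]), 45)
  expect_equal(unname(sizes["2"]), 15)
  expect_identical(dim(templates(out)), c(2L, ncol(nodeFeatures(g))))
  # templates are raw-FNC means of the members
  b1 <- names(biotypes(out))[biotypes(out) == 1]
  expect_equal(unname(templates(out)[1, ]),
               unname(colMeans(nodeFeatures(g)[match(b1, subjectIds(g)), ])))
})

test_that("training is seed-deterministic and logs an exact loss identity", {
  co <- generateCohort(tinySpec(9))
  g <- cohortGraph(co)
  cfg <- tinyConfig(3)
  m1 <- trainBiotypeModel(g, cfg)
  m2 <- trainBiotypeModel(g, cfg)
  expect_identical(biotypes(m1), biotypes(m2))
  expect_identical(embeddings(m1), embeddings(m2))
  hist <- lossHistory(m1)
  expect_equal(hist$total,
               0.01 * hist$lRec + 0.01 * hist$lCE + 0.1 * hist$lCluster,
               tolerance = 1e-12)
  expect_true(all(hist$lRec >= 0 & hist$lCE >= 0 & hist$lCluster >= 0))
})

test_that("a zero-weight cross-entropy term is inert", {
  co <- generateCohort(tinySpec(10))
  g <- cohortGraph(co)
  cfg <- tinyConfig(2, gammaCE = 0)
  m1 <- trainBiotypeModel(g, cfg)
  # with gammaCE = 0, changing the supervision mask (which nodes the CE
  # term would see) must leave embeddings and assignments untouched
  mask <- rep(FALSE, length(subjectIds(g))); mask[1:3] <- TRUE
  m2 <- trainBiotypeModel(g, cfg, ceMask = mask)
  expect_equal(embeddings(m1), embeddings(m2))
  expect_identical(biotypes(m1), biotypes(m2))
})

test_that("smoothed losses are non-increasing within each phase", {
  co <- generateCohort(tinySpec(12))
  g <- cohortGraph(co)
  cfg <- tinyConfig(4, pretrainEpochs = 30L, jointEpochs = 30L)
  hist <- lossHistory(trainBiotypeModel(g, cfg))
  smooth5 <- function(x) stats::filter(x, rep(1 / 5, 5), sides = 1)
  for (ph in c("pretrain", "joint")) {
    tot <- hist$total[hist$phase == ph]
    sm <- as.numeric(smooth5(tot))[-(1:5)]
    expect_true(all(diff(sm) <= 1e-3))
  }
})

test_that("joint deep K-means reaches the classical K-means optimum", {
  # with gammaRec = gammaCE = 0 and a hard (annealed) assignment limit,
  # the final cluster loss matches the best of 50 classical restarts on
  # the final embeddings within 2%
  co <- generateCohort(tinySpec(13))
  g <- cohortGraph(co)
  cfg <- tinyConfig(5, gammaRec = 0, gammaCE = 0,
                    pretrainEpochs = 10L, jointEpochs = 300L)
  m <- trainBiotypeModel(g, cfg)
  Zp <- embeddings(m)[patientMask(g), ]
  final <- deepKMeansLoss(Zp, centroids(m), alpha = cfg@alphaMax)
  set.seed(1)
  km <- kmeans(Zp, centers = 2, nstart = 50)
  expect_lte(final, km$tot.withinss / nrow(Zp) * 1.02 + 1e-12)
})

test_that("training is equivariant to subject permutation", {
  co <- generateCohort(tinySpec(14))
  g <- cohortGraph(co)
  cfg <- tinyConfig(6, pretrainEpochs = 10L, jointEpochs = 10L)
  m <- trainBiotypeModel(g, cfg)
  set.seed(31); perm <- sample(length(subjectIds(g)))
  gp <- induceSubgraph(g, perm)
  mp <- trainBiotypeModel(gp, cfg)
  common <- intersect(names(biotypes(m)), names(biotypes(mp)))
  expect_identical(biotypes(mp)[common], biotypes(m)[common])
})

test_that("infeasible cluster counts are rejected", {
  co <- generateCohort(tinySpec(15, nHC = 20L, nPatients = 4L))
  g <- cohortGraph(co)
  expect_error(trainBiotypeModel(g, tinyConfig(1, K = 8L)), "fewer patients")
})
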