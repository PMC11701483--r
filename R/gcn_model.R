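#' Construct a training configuration
#'
#' Defaults follow the published hyperparameters: loss weights 0.01
#' (reconstruction), 0.01 (cross-entropy), 0.1 (clustering) and Adam
#' learning rate 0.001. Architecture: two graph-convolution layers
#' d -> hiddenDim -> embeddingDim (ReLU after the first), mirrored
#' decoder, one affine classification head. Training is two-phase:
#' `pretrainEpochs` epochs without the clustering term, then
#' `jointEpochs` epochs of the full objective with the soft-min inverse
#' temperature annealed geometrically from `alpha0` by `alphaRate` up to
#' `alphaMax`.
#'
#' @param gammaRec,gammaCE,gammaCluster loss weights.
#' @param learningRate Adam step size.
#' @param K number of biotypes.
#' @param hiddenDim,embeddingDim layer widths.
#' @param pretrainEpochs,jointEpochs epoch counts for the two phases.
#' @param alpha0,alphaRate,alphaMax annealing schedule.
#' @param seed integer seed for all stochastic choices.
#' @return a [TrainingConfig-class].
#' @export
trainingConfig <- function(gammaRec = 0.01, gammaCE = 0.01,
                           gammaCluster = 0.1, learningRate = 0.001,
                           K = 2L, hiddenDim = 256L, embeddingDim = 64L,
                           pretrainEpochs = 100L, jointEpochs = 200L,
                           alpha0 = 1, alphaRate = 1.04, alphaMax = 1000,
                           seed = 1L) {
  new("TrainingConfig",
      gammaRec = gammaRec, gammaCE = gammaCE, gammaCluster = gammaCluster,
      learningRate = learningRate, K = as.integer(K),
      hiddenDim = as.integer(hiddenDim),
      embeddingDim = as.integer(embeddingDim),
      pretrainEpochs = as.integer(pretrainEpochs),
      jointEpochs = as.integer(jointEpochs),
      alpha0 = alpha0, alphaRate = alphaRate, alphaMax = alphaMax,
      seed = as.integer(seed))
}

#' One graph-convolution layer
#'
#' `activation(Ahat %*% H %*% W + b)`.
#'
#' @param H node matrix.
#' @param Ahat propagation matrix from [normalizeAdjacency()].
#' @param W weight matrix.
#' @param b optional bias row vector.
#' @param activation one of "linear", "relu", "sigmoid".
#' @return transformed node matrix.
#' @export
gcnLayer <- function(H, Ahat, W, b = NULL,
                     activation = c("linear", "relu", "sigmoid")) {
  activation <- match.arg(activation)
  if (ncol(Ahat) != nrow(H) || ncol(H) != nrow(W))
    stop("dimension mismatch in graph-convolution layer")
  out <- Ahat %*% H %*% W
  if (!is.null(b)) out <- sweep(out, 2L, b, "+")
  switch(activation,
         linear = out,
         relu = pmax(out, 0),
         sigmoid = 1 / (1 + exp(-out)))
}

#' Mean squared reconstruction loss
#' @param X,Xhat matrices of identical shape.
#' @return mean over entries of squared difference.
#' @export
reconstructionLoss <- function(X, Xhat) {
  if (!all(dim(X) == dim(Xhat)))
    stop("dimension mismatch between X and its reconstruction")
  mean((X - Xhat)^2)
}

#' Masked binary cross-entropy diagnostic loss
#'
#' Mean binary cross-entropy of `sigmoid(logit)` against the diagnosis
#' label over the masked nodes, computed in the numerically stable
#' log-sum-exp form.
#'
#' @param logits numeric vector of classifier outputs.
#' @param y labels in `{0, 1}` (1 = patient) or a factor with level
#'   "patient".
#' @param mask logical vector selecting the supervised nodes
#'   (default: all).
#' @return non-negative scalar loss.
#' @export
diagnosticCELoss <- function(logits, y, mask = NULL) {
  if (is.factor(y)) y <- as.numeric(y == "patient")
  logits <- as.numeric(logits)
  if (is.null(mask)) mask <- rep(TRUE, length(logits))
  if (!any(mask)) stop("empty mask: no nodes to compute the loss on")
  l <- logits[mask]; yy <- y[mask]
  mean(pmax(l, 0) - l * yy + log1p(exp(-abs(l))))
}

#' Deep K-means clustering loss
#'
#' Soft-min formulation
#' `L = (1/p) sum_i sum_k softmax_k(-alpha * d_ik) * d_ik` with
#' `d_ik = ||z_i - mu_k||^2`; as `alpha -> Inf` this converges to the
#' classical K-means objective (mean squared distance to the nearest
#' centroid).
#'
#' @param Z p x m embedding matrix (patients).
#' @param centroids K x m centroid matrix.
#' @param alpha inverse temperature (> 0).
#' @return non-negative scalar loss.
#' @export
deepKMeansLoss <- function(Z, centroids, alpha) {
  Z <- as.matrix(Z); centroids <- as.matrix(centroids)
  if (nrow(centroids) > nrow(Z))
    stop("infeasible: more centroids than points")
  if (!all(is.finite(Z)) || !all(is.finite(centroids)))
    stop("non-finite embeddings or centroids")
  stopifnot(alpha > 0)
  d2 <- .pairDist2(Z, centroids)
  S <- .softmaxRows(-alpha * d2)
  mean(rowSums(S * d2))
}

#' Weighted total loss
#'
#' `total = gammaRec * lRec + gammaCE * lCE + gammaCluster * lCluster`.
#'
#' @param lRec,lCE,lCluster loss components.
#' @param config a [TrainingConfig-class].
#' @return list with the components and their weighted total.
#' @export
totalLoss <- function(lRec, lCE, lCluster, config) {
  validObject(config)
  list(lRec = lRec, lCE = lCE, lCluster = lCluster,
       total = config@gammaRec * lRec + config@gammaCE * lCE +
         config@gammaCluster * lCluster)
}

## ---- internal numerics ----------------------------------------------------

.pairDist2 <- function(Z, M) {
  # squared Euclidean distances, rows of Z vs rows of M
  d2 <- outer(rowSums(Z^2), rowSums(M^2), "+") - 2 * tcrossprod(Z, M)
  pmax(d2, 0)
}

.softmaxRows <- function(L) {
  L <- L - apply(L, 1L, max)
  E <- exp(L)
  E / rowSums(E)
}

.glorot <- function(fanIn, fanOut) {
  s <- sqrt(6 / (fanIn + fanOut))
  matrix(runif(fanIn * fanOut, -s, s), fanIn, fanOut)
}

.initParams <- function(d, h, m) {
  list(W1 = .glorot(d, h), b1 = numeric(h),
       W2 = .glorot(h, m), b2 = numeric(m),
       W3 = .glorot(m, h), b3 = numeric(h),
       W4 = .glorot(h, d), b4 = numeric(d),
       wc = .glorot(m, 1L), bc = 0)
}

# forward pass + total-loss gradients; mu = NULL disables the cluster term;
# ceIntoEncoder = FALSE fits the classification head on top of the evolving
# embeddings without backpropagating the CE term into the encoder (phase 1)
.forwardBackward <- function(params, X, AX, Ahat, y, ceMask, patientIdx,
                             mu, alpha, cfg, wantGrads = TRUE,
                             ceIntoEncoder = TRUE) {
  n <- nrow(X); d <- ncol(X)
  p1 <- sweep(AX %*% params$W1, 2L, params$b1, "+")
  H1 <- pmax(p1, 0)
  P1 <- Ahat %*% H1
  Z <- sweep(P1 %*% params$W2, 2L, params$b2, "+")
  P2 <- Ahat %*% Z
  p3 <- sweep(P2 %*% params$W3, 2L, params$b3, "+")
  H3 <- pmax(p3, 0)
  P3 <- Ahat %*% H3
  Xhat <- sweep(P3 %*% params$W4, 2L, params$b4, "+")
  logits <- as.numeric(Z %*% params$wc) + params$bc

  lRec <- mean((X - Xhat)^2)
  lCE <- diagnosticCELoss(logits, y, ceMask)
  withCluster <- !is.null(mu)
  if (withCluster) {
    Zp <- Z[patientIdx, , drop = FALSE]
    d2 <- .pairDist2(Zp, mu)
    S <- .softmaxRows(-alpha * d2)
    Li <- rowSums(S * d2)
    lCluster <- mean(Li)
  } else lCluster <- 0
  total <- cfg@gammaRec * lRec + cfg@gammaCE * lCE +
    cfg@gammaCluster * lCluster
  out <- list(lRec = lRec, lCE = lCE, lCluster = lCluster, total = total,
              Z = Z, logits = logits, Xhat = Xhat)
  if (!wantGrads) return(out)

  GXhat <- cfg@gammaRec * 2 * (Xhat - X) / (n * d)
  g <- list()
  g$W4 <- crossprod(P3, GXhat); g$b4 <- colSums(GXhat)
  GP3 <- GXhat %*% t(params$W4)
  Gp3 <- (Ahat %*% GP3) * (p3 > 0)
  g$W3 <- crossprod(P2, Gp3); g$b3 <- colSums(Gp3)
  GZ <- Ahat %*% (Gp3 %*% t(params$W3))

  s <- 1 / (1 + exp(-logits))
  Glog <- numeric(n)
  nm <- sum(ceMask)
  Glog[ceMask] <- cfg@gammaCE * (s[ceMask] - y[ceMask]) / nm
  g$wc <- crossprod(Z, Glog); g$bc <- sum(Glog)
  if (ceIntoEncoder)
    GZ <- GZ + tcrossprod(Glog, as.numeric(params$wc))

  if (withCluster) {
    p <- length(patientIdx)
    Gsoft <- S * (1 - alpha * (d2 - Li)) * (cfg@gammaCluster / p)
    dZp <- 2 * (Zp * rowSums(Gsoft) - Gsoft %*% mu)
    g$mu <- 2 * (mu * colSums(Gsoft) - crossprod(Gsoft, Zp))
    GZ[patientIdx, ] <- GZ[patientIdx, ] + dZp
  }

  g$W2 <- crossprod(P1, GZ); g$b2 <- colSums(GZ)
  Gp1 <- (Ahat %*% (GZ %*% t(params$W2))) * (p1 > 0)
  g$W1 <- crossprod(AX, Gp1); g$b1 <- colSums(Gp1)
  out$grads <- g
  out
}

.adamInit <- function(params)
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)

.adamStep <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Greedy farthest-point seeding
#'
#' First seed is the point farthest from the data mean; each further seed
#' maximizes the minimum distance to the seeds chosen so far.
#'
#' @param Z p x m matrix.
#' @param K number of seeds.
#' @return integer row indices of the seeds.
#' @export
farthestPointSeeds <- function(Z, K) {
  Z <- as.matrix(Z)
  ctr <- colMeans(Z)
  seeds <- which.max(rowSums(sweep(Z, 2L, ctr)^2))
  while (length(seeds) < K) {
    d2 <- .pairDist2(Z, Z[seeds, , drop = FALSE])
    seeds <- c(seeds, which.max(apply(d2, 1L, min)))
  }
  seeds
}

#' Nearest-centroid assignment
#' @param points p x m matrix.
#' @param centroids K x m matrix.
#' @return integer vector of centroid indices (ties to the lower index).
#' @export
nearestCentroid <- function(points, centroids) {
  d2 <- .pairDist2(as.matrix(points), as.matrix(centroids))
  apply(d2, 1L, which.min)
}

## ---- training -------------------------------------------------------------

.trainCore <- function(graph, config, ceMask = NULL,
                       stopAfterPretrain = FALSE, verbose = FALSE) {
  validObject(graph); validObject(config)
  set.seed(config@seed)
  X <- nodeFeatures(graph)
  n <- nrow(X); d <- ncol(X)
  y <- as.numeric(diagnosisLabels(graph) == "patient")
  patientIdx <- which(patientMask(graph))
  if (length(patientIdx) < config@K)
    stop("fewer patients than clusters K")
  if (is.null(ceMask)) ceMask <- rep(TRUE, n)
  if (all(adjacency(graph) == 0) && config@pretrainEpochs + config@jointEpochs > 0)
    warning("training on a degenerate (edgeless) population graph")
  Ahat <- normalizeAdjacency(graph)
  # standardize features before propagation: a shared nonzero feature mean
  # would otherwise be rescaled per node by the normalized degrees and
  # dominate the embedding geometry
  sds <- apply(X, 2L, sd)
  sds[sds == 0] <- 1
  X <- scale(X, center = TRUE, scale = sds)
  attr(X, "scaled:center") <- NULL; attr(X, "scaled:scale") <- NULL
  AX <- Ahat %*% X
  params <- .initParams(d, config@hiddenDim, config@embeddingDim)
  st <- .adamInit(params)
  hist <- vector("list", config@pretrainEpochs + config@jointEpochs)

  for (e in seq_len(config@pretrainEpochs)) {
    fb <- .forwardBackward(params, X, AX, Ahat, y, ceMask, patientIdx,
                           mu = NULL, alpha = 1, cfg = config,
                           ceIntoEncoder = FALSE)
    if (!is.finite(fb$total)) stop("divergence: non-finite loss at epoch ", e)
    up <- .adamStep(params, fb$grads, st, config@learningRate)
    params <- up$params; st <- up$state
    hist[[e]] <- data.frame(epoch = e, phase = "pretrain", lRec = fb$lRec,
                            lCE = fb$lCE, lCluster = 0, total = fb$total)
    if (verbose && e %% 20 == 0)
      message(sprintf("pretrain %3d: rec %.5f ce %.5f", e, fb$lRec, fb$lCE))
  }

  fb <- .forwardBackward(params, X, AX, Ahat, y, ceMask, patientIdx,
                         mu = NULL, alpha = 1, cfg = config, wantGrads = FALSE)
  Z <- fb$Z
  if (stopAfterPretrain)
    return(list(params = params, Z = Z,
                lossHistory = do.call(rbind, hist[seq_len(config@pretrainEpochs)]),
                Ahat = Ahat, patientIdx = patientIdx))

  # centroid initialization: farthest-point seeding + classical K-means
  Zp <- Z[patientIdx, , drop = FALSE]
  seeds <- farthestPointSeeds(Zp, config@K)
  init <- Zp[seeds, , drop = FALSE] +
    matrix(rnorm(config@K * ncol(Zp), 0, 1e-8), config@K)
  mu <- kmeans(Zp, centers = init, iter.max = 100L)$centers
  params$mu <- unname(mu)
  st <- .adamInit(params)
  reseeds <- 0L

  for (e in seq_len(config@jointEpochs)) {
    alpha <- min(config@alphaMax, config@alpha0 * config@alphaRate^(e - 1))
    fb <- .forwardBackward(params, X, AX, Ahat, y, ceMask, patientIdx,
                           mu = params$mu, alpha = alpha, cfg = config)
    if (!is.finite(fb$total))
      stop("divergence: non-finite loss at joint epoch ", e)
    up <- .adamStep(params, fb$grads, st, config@learningRate)
    params <- up$params; st <- up$state
    hist[[config@pretrainEpochs + e]] <-
      data.frame(epoch = config@pretrainEpochs + e, phase = "joint",
                 lRec = fb$lRec, lCE = fb$lCE, lCluster = fb$lCluster,
                 total = fb$total)
    if (e %% 10 == 0 || e == config@jointEpochs) {
      hard <- nearestCentroid(fb$Z[patientIdx, , drop = FALSE], params$mu)
      empty <- setdiff(seq_len(config@K), unique(hard))
      if (length(empty) > 0) {
        reseeds <- reseeds + 1L
        if (reseeds >= 3L)
          stop("empty cluster recurred ", reseeds, " times; rerun advised")
        Zp <- fb$Z[patientIdx, , drop = FALSE]
        d2 <- .pairDist2(Zp, params$mu)
        for (k in empty)
          params$mu[k, ] <- Zp[which.max(apply(d2, 1L, min)), ]
      }
    }
    if (verbose && e %% 20 == 0)
      message(sprintf("joint %3d: rec %.5f ce %.5f clu %.5f", e,
                      fb$lRec, fb$lCE, fb$lCluster))
  }

  fb <- .forwardBackward(params, X, AX, Ahat, y, ceMask, patientIdx,
                         mu = params$mu, alpha = config@alphaMax,
                         cfg = config, wantGrads = FALSE)
  list(params = params, Z = fb$Z, lossHistory = do.call(rbind, hist),
       Ahat = Ahat, patientIdx = patientIdx)
}

#' Train the biotype-discovery model
#'
#' Phase 1 pretrains the graph-convolutional autoencoder and the
#' diagnostic classification head (clustering term inactive); centroids
#' are then initialized by greedy farthest-point seeding followed by
#' classical K-means on the pretrained patient embeddings; phase 2
#' jointly minimizes `gammaRec * Lrec + gammaCE * LCE +
#' gammaCluster * Lcluster` with the soft-min inverse temperature
#' annealed geometrically. Biotype labels are renumbered so biotype 1 is
#' the largest cluster; templates are per-biotype means of the raw FNC
#' vectors.
#'
#' @param graph a [PopulationGraph-class].
#' @param config a [TrainingConfig-class].
#' @param ceMask optional logical vector; only these nodes contribute to
#'   the cross-entropy term (cross-validation masking).
#' @param verbose print loss summaries during training.
#' @return a [BiotypeModel-class].
#' @export
trainBiotypeModel <- function(graph, config = trainingConfig(),
                              ceMask = NULL, verbose = FALSE) {
  core <- .trainCore(graph, config, ceMask = ceMask, verbose = verbose)
  model <- new("BiotypeModel",
               params = core$params, embeddings = unname(core$Z),
               centroids = unname(core$params$mu),
               assignments = setNames(rep(1L, length(core$patientIdx)),
                                      subjectIds(graph)[core$patientIdx]),
               templates = matrix(0, 0, 0), config = config,
               lossHistory = core$lossHistory,
               ids = subjectIds(graph), patientMask = patientMask(graph))
  assignBiotypes(model, graph)
}

#' Assign biotypes and compute FNC templates
#'
#' Each patient goes to its nearest centroid in embedding space; labels
#' are renumbered by descending cluster size (ties broken by descending
#' centroid norm); templates are the per-biotype means of the raw FNC
#' vectors (never of embeddings).
#'
#' @param model a [BiotypeModel-class].
#' @param graph the [PopulationGraph-class] the model was trained on
#'   (source of the raw FNC vectors).
#' @return the model with `assignments`, `centroids` (reordered) and
#'   `templates` filled in.
#' @export
assignBiotypes <- function(model, graph) {
  patientIdx <- which(model@patientMask)
  Zp <- model@embeddings[patientIdx, , drop = FALSE]
  hard <- nearestCentroid(Zp, model@centroids)
  K <- nrow(model@centroids)
  sizes <- tabulate(hard, nbins = K)
  if (any(sizes == 0))
    stop("empty cluster after assignment; rerun advised")
  norms <- sqrt(rowSums(model@centroids^2))
  ord <- order(-sizes, -norms)
  relabel <- integer(K); relabel[ord] <- seq_len(K)
  newAssign <- relabel[hard]
  Xp <- nodeFeatures(graph)[patientIdx, , drop = FALSE]
  tmpl <- do.call(rbind, lapply(seq_len(K), function(k)
    colMeans(Xp[newAssign == k, , drop = FALSE])))
  rownames(tmpl) <- paste0("biotype", seq_len(K))
  model@assignments <- setNames(as.integer(newAssign),
                                model@ids[patientIdx])
  model@centroids <- model@centroids[ord, , drop = FALSE]
  model@templates <- tmpl
  validObject(model)
  model
}

#' @rdname BiotypeGraph-generics
#' @export
setMethod("embeddings", "BiotypeModel", function(object) object@embeddings)

#' @rdname BiotypeGraph-generics
#' @export
setMethod("centroids", "BiotypeModel", function(object) object@centroids)

#' @rdname BiotypeGraph-generics
#' @export
setMethod("biotypes", "BiotypeModel", function(object) object@assignments)

#' @rdname BiotypeGraph-generics
#' @export
setMethod("templates", "BiotypeModel", function(object) object@templates)

#' @rdname BiotypeGraph-generics
#' @export
setMethod("lossHistory", "BiotypeModel", function(object) object@lossHistory)

setMethod("show", "BiotypeModel", function(object) {
  sizes <- table(object@assignments)
  cat("BiotypeModel: K =", nrow(object@centroids),
      "| embedding dim", ncol(object@embeddings),
      "| biotype sizes:", paste(sizes, collapse = "/"), "\n")
  if (nrow(object@lossHistory) > 0) {
    last <- object@lossHistory[nrow(object@lossHistory), ]
    cat(sprintf("final losses: rec %.5f ce %.5f cluster %.5f total %.6f\n",
                last$lRec, last$lCE, last$lCluster, last$total))
  }
})
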