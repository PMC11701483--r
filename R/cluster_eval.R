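#' Within-cluster sum of squares (CSS)
#'
#' `sum_i ||x_i - mu_{c(i)}||^2` over all points.
#'
#' @param points p x m matrix.
#' @param assignments integer cluster labels (1..K) per point.
#' @param centroids K x m matrix; if NULL, cluster means are used.
#' @return non-negative scalar.
#' @export
clusterSS <- function(points, assignments, centroids = NULL) {
  points <- as.matrix(points)
  if (length(assignments) != nrow(points) || anyNA(assignments))
    stop("every point must carry a cluster assignment")
  K <- max(assignments)
  if (is.null(centroids))
    centroids <- do.call(rbind, lapply(seq_len(K), function(k)
      colMeans(points[assignments == k, , drop = FALSE])))
  sum((points - centroids[assignments, , drop = FALSE])^2)
}

#' CSS curve over candidate cluster counts
#'
#' Best-of-restarts K-means CSS for each K (K = 1 gives the total sum of
#' squares around the grand mean).
#'
#' @param points p x m matrix.
#' @param kValues candidate cluster counts.
#' @param nstart K-means restarts per K.
#' @param seed integer seed.
#' @return named numeric vector, one CSS per K.
#' @export
cssCurve <- function(points, kValues = 1:8, nstart = 10L, seed = 1L) {
  points <- as.matrix(points)
  set.seed(seed)
  vapply(kValues, function(k) {
    if (k == 1) {
      sum(sweep(points, 2L, colMeans(points))^2)
    } else {
      km <- kmeans(points, centers = k, nstart = nstart, iter.max = 50L)
      clusterSS(points, km$cluster, km$centers)
    }
  }, numeric(1)) -> css
  names(css) <- kValues
  css
}

#' Elbow selection on a CSS curve
#'
#' Normalizes both axes to `[0, 1]` and returns the K whose point has
#' maximal perpendicular distance to the chord joining the first and
#' last curve points (ties to the smaller K). A degenerate (exactly
#' linear) curve returns the smallest interior K with a warning.
#'
#' @param css named numeric vector of CSS values (names = K).
#' @return the selected integer K.
#' @export
selectKElbow <- function(css) {
  if (length(css) < 3) stop("need a curve over at least 3 K values")
  if (any(!is.finite(css))) stop("non-finite CSS values")
  kv <- as.numeric(names(css))
  if (anyNA(kv)) kv <- seq_along(css)
  x <- (kv - min(kv)) / (max(kv) - min(kv))
  y <- (css - min(css)) / if (diff(range(css)) > 0) diff(range(css)) else 1
  # distance from (x, y) to the chord (x1,y1)-(xn,yn)
  dx <- x[length(x)] - x[1]; dy <- y[length(y)] - y[1]
  dist <- abs(dy * x - dx * y + dx * y[1] - dy * x[1]) / sqrt(dx^2 + dy^2)
  if (max(dist) < 1e-12) {
    warning("degenerate (linear) CSS curve; returning the smallest interior K")
    return(as.integer(kv[2]))
  }
  as.integer(kv[which.max(dist)])
}

#' Davies-Bouldin index
#'
#' `(1/K) sum_k max_{j != k} (s_k + s_j) / d_kj` with `s_k` the mean
#' distance of cluster members to their centroid and `d_kj` the centroid
#' separation. Lower is better.
#'
#' @param points p x m matrix.
#' @param assignments integer labels 1..K (every cluster non-empty).
#' @return non-negative scalar.
#' @export
daviesBouldin <- function(points, assignments) {
  points <- as.matrix(points)
  K <- max(assignments)
  if (K < 2) stop("need at least 2 clusters")
  ctr <- do.call(rbind, lapply(seq_len(K), function(k)
    colMeans(points[assignments == k, , drop = FALSE])))
  s <- vapply(seq_len(K), function(k) {
    mem <- points[assignments == k, , drop = FALSE]
    mean(sqrt(rowSums(sweep(mem, 2L, ctr[k, ])^2)))
  }, numeric(1))
  D <- as.matrix(dist(ctr))
  if (any(D[upper.tri(D)] == 0))
    stop("coincident centroids: Davies-Bouldin ratio undefined")
  R <- outer(s, s, "+") / D
  diag(R) <- -Inf
  mean(apply(R, 1L, max))
}

#' Calinski-Harabasz index
#'
#' `[between-group SS / (K - 1)] / [within-group SS / (p - K)]`; higher is
#' better. Zero within-group scatter returns `Inf`.
#'
#' @param points p x m matrix.
#' @param assignments integer labels 1..K.
#' @return non-negative scalar (possibly `Inf`).
#' @export
calinskiHarabasz <- function(points, assignments) {
  points <- as.matrix(points)
  K <- max(assignments)
  p <- nrow(points)
  if (K < 2 || p <= K) stop("need K >= 2 and more points than clusters")
  grand <- colMeans(points)
  within <- 0; between <- 0
  for (k in seq_len(K)) {
    mem <- points[assignments == k, , drop = FALSE]
    ck <- colMeans(mem)
    within <- within + sum(sweep(mem, 2L, ck)^2)
    between <- between + nrow(mem) * sum((ck - grand)^2)
  }
  if (within == 0) return(Inf)
  (between / (K - 1)) / (within / (p - K))
}

#' Adjusted Rand index between two labelings
#' @param a,b label vectors of equal length.
#' @return ARI in [-1, 1].
#' @export
adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)

#' Internal validity summary of one clustering
#' @param points feature matrix the clustering lives in.
#' @param assignments integer labels.
#' @param method method name carried in the output.
#' @param truth optional ground-truth labels for ARI.
#' @return one-row data.frame (method, K, css, dbi, chi, ari).
#' @export
clusterQuality <- function(points, assignments, method = "method",
                           truth = NULL) {
  data.frame(method = method, K = max(assignments),
             css = clusterSS(points, assignments),
             dbi = daviesBouldin(points, assignments),
             chi = calinskiHarabasz(points, assignments),
             ari = if (is.null(truth)) NA_real_ else
               adjustedRand(assignments, truth),
             stringsAsFactors = FALSE)
}

#' Run the baseline clusterers alongside the graph model
#'
#' Comparators: (1) Ward agglomerative clustering and (2) conventional
#' K-means, both on raw FNC; (3) a graph-free autoencoder with the same
#' deep K-means loss (identity propagation matrix); (4) the graph
#' autoencoder trained without the clustering and cross-entropy terms
#' followed by classical K-means on its embeddings; (5) the full model.
#' Indices are computed in the feature space each method clusters
#' (raw FNC for 1-2, learned embeddings for 3-5).
#'
#' @param graph a [PopulationGraph-class].
#' @param config a [TrainingConfig-class].
#' @param truth optional planted subtype labels over patients (for ARI).
#' @param methods subset of methods to run.
#' @return list with `quality` (tidy data.frame) and `assignments`
#'   (list of per-method patient label vectors).
#' @export
runBaselines <- function(graph, config = trainingConfig(), truth = NULL,
                         methods = c("agglomerative", "kmeans",
                                     "dnn_kmeans", "gcn_kmeans", "gcn_biotype")) {
  pat <- which(patientMask(graph))
  Xp <- nodeFeatures(graph)[pat, , drop = FALSE]
  K <- config@K
  rows <- list(); assigns <- list()
  for (m in methods) {
    res <- tryCatch(switch(m,
      agglomerative = {
        cl <- cutree(hclust(dist(Xp), method = "ward.D2"), k = K)
        list(points = Xp, cl = cl)
      },
      kmeans = {
        set.seed(config@seed)
        cl <- kmeans(Xp, centers = K, nstart = 20L)$cluster
        list(points = Xp, cl = cl)
      },
      dnn_kmeans = {
        g0 <- graph
        g0@A <- matrix(0, nrow(g0@A), ncol(g0@A))  # identity propagation
        fit <- suppressWarnings(trainBiotypeModel(g0, config))
        list(points = embeddings(fit)[pat, , drop = FALSE],
             cl = unname(biotypes(fit)))
      },
      gcn_kmeans = {
        cfg <- config
        cfg@gammaCluster <- 0; cfg@gammaCE <- 0
        core <- .trainCore(graph, cfg, stopAfterPretrain = TRUE)
        Zp <- core$Z[pat, , drop = FALSE]
        set.seed(config@seed)
        list(points = Zp,
             cl = kmeans(Zp, centers = K, nstart = 20L)$cluster)
      },
      gcn_biotype = {
        fit <- trainBiotypeModel(graph, config)
        list(points = embeddings(fit)[pat, , drop = FALSE],
             cl = unname(biotypes(fit)))
      },
      stop("unknown method ", m)), error = function(e) e)
    if (inherits(res, "error")) {
      warning("method ", m, " failed: ", conditionMessage(res))
      next
    }
    rows[[m]] <- clusterQuality(res$points, res$cl, method = m, truth = truth)
    assigns[[m]] <- res$cl
  }
  list(quality = do.call(rbind, c(rows, make.row.names = FALSE)),
       assignments = assigns)
}

#' Align cluster labels of one template set to a reference
#'
#' Finds the label permutation maximizing the summed Pearson correlation
#' between matched template rows (exhaustive for K <= 5, greedy above).
#'
#' @param tmpl K x d template matrix to relabel.
#' @param ref K x d reference template matrix.
#' @return integer permutation `perm` such that `tmpl[perm[k], ]` matches
#'   `ref[k, ]`.
#' @export
alignTemplates <- function(tmpl, ref) {
  K <- nrow(ref)
  cc <- matrix(0, K, K)
  for (a in seq_len(K)) for (b in seq_len(K))
    cc[a, b] <- cor(ref[a, ], tmpl[b, ])
  if (K <= 5) {
    perms <- .permutations(K)
    scores <- apply(perms, 1L, function(p) sum(cc[cbind(seq_len(K), p)]))
    as.integer(unname(perms[which.max(scores), ]))
  } else {
    perm <- integer(K); used <- logical(K)
    for (a in order(-apply(cc, 1L, max))) {
      b <- order(-cc[a, ])
      b <- b[!used[b]][1]
      perm[a] <- b; used[b] <- TRUE
    }
    perm
  }
}

.permutations <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(K - 1L)
  do.call(rbind, lapply(seq_len(K), function(pos) {
    cbind(pos, sub + (sub >= pos))
  }))
}

#' Fold-stability of biotype FNC templates
#'
#' Repeatedly leaves one patient fold out, retrains on the retained
#' subjects, aligns the fold's biotype labels to the full-data model by
#' maximal template correlation, and reports the Pearson correlation
#' between each fold template and the matching full-data template.
#'
#' @param graph a [PopulationGraph-class].
#' @param config a [TrainingConfig-class].
#' @param folds number of folds over patients.
#' @param realizations number of repeated fold draws.
#' @param refModel optional pre-trained full-data model (avoids refit).
#' @return tidy data.frame (realization, fold, biotype, r).
#' @export
kfoldStability <- function(graph, config = trainingConfig(), folds = 10L,
                           realizations = 1L, refModel = NULL) {
  stopifnot(folds >= 2L)
  if (is.null(refModel)) refModel <- trainBiotypeModel(graph, config)
  refTmpl <- templates(refModel)
  pat <- which(patientMask(graph))
  out <- list()
  for (r in seq_len(realizations)) {
    set.seed(config@seed + 1000L * r)
    foldId <- sample(rep_len(seq_len(folds), length(pat)))
    for (f in seq_len(folds)) {
      keep <- rep(TRUE, nrow(nodeFeatures(graph)))
      keep[pat[foldId == f]] <- FALSE
      sub <- induceSubgraph(graph, keep)
      fit <- tryCatch(trainBiotypeModel(sub, config), error = function(e) e)
      if (inherits(fit, "error")) {
        warning("fold ", f, " failed and was excluded: ",
                conditionMessage(fit))
        next
      }
      tmpl <- templates(fit)
      perm <- alignTemplates(tmpl, refTmpl)
      for (k in seq_len(nrow(refTmpl)))
        out[[length(out) + 1L]] <- data.frame(
          realization = r, fold = f, biotype = k,
          r = cor(refTmpl[k, ], tmpl[perm[k], ]))
    }
  }
  do.call(rbind, out)
}

#' Random-feature ablation
#'
#' Retrains the model on the identical graph topology but with node
#' features replaced by Gaussian noise of matched marginal moments; on
#' planted data the recovered structure should vanish (ARI near 0).
#'
#' @param graph a [PopulationGraph-class].
#' @param config a [TrainingConfig-class].
#' @param truth planted subtype labels over patients.
#' @return list with `quality` rows for the FNC and random runs and the
#'   two ARI values.
#' @export
randomFeatureAblation <- function(graph, config = trainingConfig(),
                                  truth = NULL) {
  fitReal <- trainBiotypeModel(graph, config)
  X <- nodeFeatures(graph)
  set.seed(config@seed + 77L)
  gNull <- graph
  gNull@X <- matrix(rnorm(length(X), mean = mean(X), sd = sd(X)),
                    nrow = nrow(X),
                    dimnames = dimnames(X))
  fitNull <- trainBiotypeModel(gNull, config)
  pat <- which(patientMask(graph))
  q <- rbind(
    clusterQuality(embeddings(fitReal)[pat, , drop = FALSE],
                   unname(biotypes(fitReal)), "fnc_features", truth),
    clusterQuality(embeddings(fitNull)[pat, , drop = FALSE],
                   unname(biotypes(fitNull)), "random_features", truth))
  list(quality = q,
       ariFNC = q$ari[1], ariRandom = q$ari[2])
}

#' Pretrain-phase model selection for K
#'
#' Runs phase-1 training (reconstruction + diagnostic cross-entropy; the
#' clustering term needs K and is therefore inactive during selection),
#' computes the best-of-restarts K-means CSS curve on the patient
#' embeddings over the candidate K values, and applies the elbow rule.
#'
#' @param graph a [PopulationGraph-class].
#' @param config a [TrainingConfig-class].
#' @param kValues candidate K values.
#' @param nstart K-means restarts per K.
#' @return list with `k` (selected), `css` (the curve) and `Z` (patient
#'   embeddings).
#' @export
selectBiotypeK <- function(graph, config = trainingConfig(),
                           kValues = 1:8, nstart = 10L) {
  core <- .trainCore(graph, config, stopAfterPretrain = TRUE)
  Zp <- core$Z[core$patientIdx, , drop = FALSE]
  css <- cssCurve(Zp, kValues, nstart = nstart, seed = config@seed)
  list(k = selectKElbow(css), css = css, Z = Zp)
}
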