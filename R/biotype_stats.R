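#' Project subjects onto biotype templates
#'
#' Assigns each subject to the biotype whose mean-FNC template is nearest
#' in Euclidean distance (exact ties go to biotype 1, the lower index).
#'
#' @param fnc n x d FNC matrix (or a single vector).
#' @param templates K x d template matrix (e.g. [templates()] of a model).
#' @return integer biotype labels.
#' @export
projectToTemplates <- function(fnc, templates) {
  if (is.null(dim(fnc))) fnc <- matrix(fnc, nrow = 1)
  fnc <- as.matrix(fnc)
  if (ncol(fnc) != ncol(templates))
    stop("projection error: subject FNC dimension ", ncol(fnc),
         " does not match template dimension ", ncol(templates))
  d2 <- .pairDist2(fnc, as.matrix(templates))
  apply(d2, 1L, which.min)  # which.min resolves ties to the lower index
}

#' Covariate-adjusted two-sample t-test
#'
#' Least squares of the measure on intercept + group indicator +
#' covariates; t and two-sided p come from the group coefficient. With no
#' covariates this equals the classical pooled two-sample t-test.
#'
#' @param values numeric outcome vector.
#' @param groups two-level factor (or coercible).
#' @param covariates optional numeric matrix/data.frame of nuisance
#'   covariates (categorical ones pre-encoded).
#' @return one-row data.frame (measure, group1, group2, t, p, cohensD).
#' @param measure label carried into the output.
#' @export
adjustedTwoSampleT <- function(values, groups, covariates = NULL,
                               measure = "measure") {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (min(table(groups)) < 2) stop("both groups need at least 2 subjects")
  g <- as.numeric(groups == levels(groups)[1])  # 1 = first level
  D <- cbind(1, g)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    D <- cbind(D, covariates)
  }
  if (qr(D)$rank < ncol(D)) stop("design error: collinear covariates")
  fit <- lm.fit(D, values)
  df <- length(values) - ncol(D)
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(chol(crossprod(D)))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  tval <- fit$coefficients[2] / se
  data.frame(measure = measure,
             group1 = levels(groups)[1], group2 = levels(groups)[2],
             t = unname(tval), p = unname(2 * pt(-abs(tval), df)),
             cohensD = cohensD(values, groups),
             stringsAsFactors = FALSE)
}

#' Cohen's d effect size
#'
#' Mean difference (first level minus second) over the df-weighted pooled
#' standard deviation.
#'
#' @param values numeric outcome vector.
#' @param groups two-level factor.
#' @return signed effect size d.
#' @export
cohensD <- function(values, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  x <- values[groups == levels(groups)[1]]
  y <- values[groups == levels(groups)[2]]
  if (length(x) < 2 || length(y) < 2) stop("both groups need at least 2 subjects")
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0) stop("undefined effect size: zero pooled SD")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate correction with monotonicity enforcement;
#' adjusted values are never below the raw values.
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted p-values, order-preserving.
#' @export
fdrAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Top discriminative FNC edges by two-sample t-tests
#'
#' Per-edge covariate-adjusted two-sample t statistics between two
#' subject groups, ranked by |t|. The default contrast in downstream
#' pipelines is each biotype against healthy controls; a
#' biotype-versus-biotype contrast is just a different `groups` vector.
#'
#' @param fnc n x d FNC matrix.
#' @param groups two-level factor over the rows of `fnc`.
#' @param k number of top edges to return (truncated to d with a warning).
#' @param covariates optional nuisance design (residualized out of the
#'   features first, per [regressCovariates()]).
#' @return data.frame (rank, edge, edgeIdx, i, j, t, p) of the top-k edges.
#' @export
topDiscriminativeFNC <- function(fnc, groups, k = 100L, covariates = NULL) {
  fnc <- as.matrix(fnc)
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (min(table(groups)) < 3) stop("both groups need at least 3 subjects")
  if (k > ncol(fnc)) {
    warning("k exceeds the number of edges; truncating to ", ncol(fnc))
    k <- ncol(fnc)
  }
  if (!is.null(covariates))
    fnc <- regressCovariates(fnc, cbind(1, as.matrix(covariates)))
  aIdx <- groups == levels(groups)[1]
  n1 <- sum(aIdx); n2 <- sum(!aIdx)
  m1 <- colMeans(fnc[aIdx, , drop = FALSE])
  m2 <- colMeans(fnc[!aIdx, , drop = FALSE])
  v1 <- apply(fnc[aIdx, , drop = FALSE], 2L, var)
  v2 <- apply(fnc[!aIdx, , drop = FALSE], 2L, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  pval <- 2 * pt(-abs(tval), df)
  C <- (1 + sqrt(1 + 8 * ncol(fnc))) / 2
  idx <- edgeIndex(as.integer(round(C)))
  ord <- order(-abs(tval))
  top <- ord[seq_len(k)]
  data.frame(rank = seq_len(k),
             edge = idx$edge[top], edgeIdx = top,
             i = idx$i[top], j = idx$j[top],
             t = unname(tval[top]), p = unname(pval[top]),
             stringsAsFactors = FALSE)
}

#' Network-block contribution of an edge set
#'
#' Counts how many edges of a discriminative set fall into each unordered
#' pair of functional networks (upper triangle plus diagonal of the
#' network-by-network matrix).
#'
#' @param edgeSet data.frame with component columns `i`, `j` (as returned
#'   by [topDiscriminativeFNC()]) or a 2-column matrix.
#' @param partition a [NetworkPartition-class].
#' @return symmetric network x network count matrix; the counts over
#'   unordered pairs sum to the edge-set size.
#' @export
networkContribution <- function(edgeSet, partition) {
  if (is.matrix(edgeSet)) edgeSet <- data.frame(i = edgeSet[, 1], j = edgeSet[, 2])
  C <- componentCount(partition)
  if (any(edgeSet$i < 1 | edgeSet$i > C | edgeSet$j < 1 | edgeSet$j > C))
    stop("partition error: component index outside the partition")
  nets <- partition@networks
  counts <- matrix(0L, length(nets), length(nets),
                   dimnames = list(nets, nets))
  a <- as.integer(partition@labels[edgeSet$i])
  b <- as.integer(partition@labels[edgeSet$j])
  lo <- pmin(a, b); hi <- pmax(a, b)
  for (r in seq_along(lo)) {
    counts[lo[r], hi[r]] <- counts[lo[r], hi[r]] + 1L
    if (lo[r] != hi[r]) counts[hi[r], lo[r]] <- counts[hi[r], lo[r]] + 1L
  }
  counts
}

.upperWithDiag <- function(M) M[upper.tri(M, diag = TRUE)]

#' Cross-cohort consistency of biotype patterns
#'
#' Pearson correlation between the vectorized network-contribution
#' matrices of two cohorts (28 unordered network-pair cells in the
#' 7-network layout), and between their whole-FNC biotype-minus-control
#' mean-difference vectors.
#'
#' @param contribA,contribB network contribution matrices.
#' @param diffA,diffB optional whole-FNC mean-difference vectors.
#' @return data.frame (quantity, r, p).
#' @export
crossCohortConsistency <- function(contribA, contribB,
                                   diffA = NULL, diffB = NULL) {
  va <- .upperWithDiag(contribA); vb <- .upperWithDiag(contribB)
  if (sd(va) == 0 || sd(vb) == 0)
    stop("undefined correlation: zero-variance contribution vector")
  ct <- cor.test(va, vb)
  out <- data.frame(quantity = "network_contribution",
                    r = unname(ct$estimate), p = ct$p.value,
                    stringsAsFactors = FALSE)
  if (!is.null(diffA)) {
    if (sd(diffA) == 0 || sd(diffB) == 0)
      stop("undefined correlation: zero-variance difference vector")
    ct2 <- cor.test(diffA, diffB)
    out <- rbind(out, data.frame(quantity = "fnc_difference",
                                 r = unname(ct2$estimate), p = ct2$p.value,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Overlap of two top-edge sets
#'
#' Intersection of two discriminative edge sets, ordered by the canonical
#' edge index.
#'
#' @param setA,setB integer edge indices or data.frames with `edgeIdx`.
#' @return sorted integer vector of shared edge indices.
#' @export
overlapTopSets <- function(setA, setB) {
  ia <- if (is.data.frame(setA)) setA$edgeIdx else setA
  ib <- if (is.data.frame(setB)) setB$edgeIdx else setB
  sort(intersect(ia, ib))
}

#' Correlations between discriminative edges and symptom/cognition scales
#'
#' Pearson r and p for every (edge, scale) pair, FDR-adjusted within the
#' returned table. Constant columns are flagged per pair, not fatal.
#'
#' @param fncSubset n x s matrix of edge values (columns named by edge).
#' @param scales n x q matrix/data.frame of scale scores.
#' @return data.frame (edge, scale, r, p, pFDR, note).
#' @export
fncScaleCorrelations <- function(fncSubset, scales) {
  fncSubset <- as.matrix(fncSubset)
  scales <- as.data.frame(scales)
  rows <- list()
  for (e in seq_len(ncol(fncSubset))) for (s in seq_len(ncol(scales))) {
    x <- fncSubset[, e]; y <- scales[[s]]
    ok <- complete.cases(x, y)
    note <- ""
    if (sum(ok) < 4) {
      r <- NA_real_; p <- NA_real_; note <- "fewer than 4 complete pairs"
    } else if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      r <- NA_real_; p <- NA_real_; note <- "constant column"
    } else {
      ct <- cor.test(x[ok], y[ok])
      r <- unname(ct$estimate); p <- ct$p.value
    }
    rows[[length(rows) + 1L]] <- data.frame(
      edge = colnames(fncSubset)[e] %||% paste0("edge", e),
      scale = names(scales)[s] %||% paste0("scale", s),
      r = r, p = p, note = note, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$pFDR <- NA_real_
  ok <- !is.na(out$p)
  out$pFDR[ok] <- fdrAdjust(out$p[ok])
  out[, c("edge", "scale", "r", "p", "pFDR", "note")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
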