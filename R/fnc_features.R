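#' Canonical 7-network names
#'
#' Subcortical, auditory, sensorimotor, visual, cognitive control,
#' default mode and cerebellar networks, in the canonical order of the
#' 53-component NeuroMark layout.
#' @export
NEUROMARK_NETWORKS <- c("SC", "AU", "SM", "VI", "CC", "DM", "CB")

#' Construct a component-to-network partition
#'
#' @param sizes integer vector of components per network, in network order.
#'   The default (5, 2, 9, 9, 17, 7, 4) is the 53-component, 7-network
#'   NeuroMark layout.
#' @param networks network names, one per entry of `sizes`.
#' @return a [NetworkPartition-class] object.
#' @examples
#' p <- networkPartition()
#' componentCount(p)  # 53
#' @export
networkPartition <- function(sizes = c(5L, 2L, 9L, 9L, 17L, 7L, 4L),
                             networks = NEUROMARK_NETWORKS[seq_along(sizes)]) {
  stopifnot(length(sizes) == length(networks), all(sizes >= 1))
  labels <- factor(rep(networks, times = sizes), levels = networks)
  new("NetworkPartition", labels = labels, networks = networks)
}

#' Proportionally scaled component partition
#'
#' Allocates `C` components to the 7 canonical networks in proportion to
#' the 53-component layout (largest-remainder rounding), so that compact
#' cohorts keep the full layout's network-block geometry.
#'
#' @param C total component count.
#' @return a [NetworkPartition-class].
#' @examples
#' networkSizes(scaledPartition(20))  # 2,1,3,3,6,3,2
#' @export
scaledPartition <- function(C) {
  ref <- c(5, 2, 9, 9, 17, 7, 4)
  raw <- C * ref / sum(ref)
  sizes <- floor(raw)
  rem <- C - sum(sizes)
  if (rem > 0) {
    ord <- order(raw - sizes, decreasing = TRUE)
    sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1L
  }
  keep <- sizes > 0
  networkPartition(as.integer(sizes[keep]), NEUROMARK_NETWORKS[keep])
}

#' Read a partition from a two-column delimited table (component, network)
#' @param path file with columns `component` and `network`.
#' @return a [NetworkPartition-class].
#' @export
readPartition <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("component", "network") %in% names(tab)))
    stop("partition table needs columns 'component' and 'network'")
  tab <- tab[order(tab$component), ]
  networks <- unique(tab$network)
  new("NetworkPartition",
      labels = factor(tab$network, levels = networks), networks = networks)
}

#' @rdname BiotypeGraph-generics
#' @export
setMethod("componentCount", "NetworkPartition",
          function(object) length(object@labels))

#' @rdname BiotypeGraph-generics
#' @export
setMethod("networkSizes", "NetworkPartition",
          function(object) table(object@labels))

setMethod("show", "NetworkPartition", function(object) {
  cat("NetworkPartition:", length(object@labels), "components in",
      length(object@networks), "networks\n")
  print(table(object@labels))
})

#' Upper-triangle edge index in canonical order
#'
#' Fixed row-major order (i ascending, then j > i); every vectorized FNC,
#' template and overlap computation in the package uses this order.
#'
#' @param C component count.
#' @return data.frame with columns `i`, `j`, `edge` (name "compI_compJ").
#' @export
edgeIndex <- function(C) {
  stopifnot(C >= 2)
  i <- rep.int(seq_len(C - 1L), times = (C - 1L):1L)
  j <- unlist(lapply(seq_len(C - 1L), function(a) (a + 1L):C), use.names = FALSE)
  data.frame(i = i, j = j, edge = paste0("comp", i, "_comp", j),
             stringsAsFactors = FALSE)
}

#' Compute functional network connectivity from component time courses
#'
#' Pearson correlation between all pairs of component time courses,
#' giving one symmetric C x C matrix per subject.
#'
#' @param timecourses C x T matrix, one row per component.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
computeFNC <- function(timecourses) {
  tc <- as.matrix(timecourses)
  if (ncol(tc) < 3)
    stop("insufficient samples: need at least 3 time points, got ", ncol(tc))
  v <- apply(tc, 1L, var)
  if (any(v == 0))
    stop("zero-variance component(s): ", paste(which(v == 0), collapse = ", "))
  r <- cor(t(tc))
  diag(r) <- 1
  r
}

#' Vectorize a symmetric FNC matrix into its upper-triangle features
#'
#' Extracts the strict upper triangle in the canonical [edgeIndex()] order;
#' a 53 x 53 matrix yields 53*52/2 = 1378 features.
#'
#' @param mat symmetric C x C matrix.
#' @param tol symmetry tolerance.
#' @return named numeric vector of length C(C-1)/2.
#' @export
vectorizeFNC <- function(mat, tol = 1e-8) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat) || max(abs(mat - t(mat))) > tol)
    stop("FNC matrix must be symmetric within ", tol)
  idx <- edgeIndex(nrow(mat))
  out <- mat[cbind(idx$i, idx$j)]
  names(out) <- idx$edge
  out
}

#' Rebuild a symmetric matrix from an upper-triangle FNC vector
#'
#' Inverse of [vectorizeFNC()]; the diagonal is set to 1.
#'
#' @param values vector of length C(C-1)/2.
#' @return symmetric C x C matrix with unit diagonal.
#' @export
unvectorizeFNC <- function(values) {
  d <- length(values)
  C <- (1 + sqrt(1 + 8 * d)) / 2
  if (abs(C - round(C)) > 1e-9)
    stop("length ", d, " is not C(C-1)/2 for any integer C")
  C <- as.integer(round(C))
  idx <- edgeIndex(C)
  mat <- diag(1, C)
  mat[cbind(idx$i, idx$j)] <- values
  mat[cbind(idx$j, idx$i)] <- values
  mat
}

#' Residualize features on nuisance covariates
#'
#' Least-squares regression of every feature column on the design matrix;
#' returns the residuals. Used to remove site/scanner and mean framewise
#' displacement effects before statistical analysis.
#'
#' @param features n x d numeric matrix.
#' @param design n x q design matrix including an intercept column;
#'   categorical covariates must be pre-encoded as indicators.
#' @return n x d matrix of residuals (orthogonal to the design columns).
#' @export
regressCovariates <- function(features, design) {
  features <- as.matrix(features)
  design <- as.matrix(design)
  if (nrow(features) != nrow(design))
    stop("features and design must have the same number of rows")
  if (nrow(design) <= ncol(design) + 1)
    stop("need more observations than covariates")
  hasIntercept <- any(apply(design, 2L, function(col) sd(col) == 0 && col[1] != 0))
  if (!hasIntercept)
    stop("design must include an intercept column")
  qrD <- qr(design)
  if (qrD$rank < ncol(design)) {
    dep <- colnames(design)[qrD$pivot[(qrD$rank + 1):ncol(design)]]
    if (is.null(dep)) dep <- qrD$pivot[(qrD$rank + 1):ncol(design)]
    stop("collinear design; dependent columns: ", paste(dep, collapse = ", "))
  }
  res <- qr.resid(qrD, features)
  dimnames(res) <- dimnames(features)
  res
}

#' Fisher z-transform and inverse
#' @param r correlations in (-1, 1).
#' @return atanh(r).
#' @export
fisherZ <- function(r) atanh(r)

#' @rdname fisherZ
#' @param z Fisher-z values.
#' @export
fisherZInv <- function(z) tanh(z)
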