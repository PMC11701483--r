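#' Build the population graph
#'
#' Subjects are nodes with their FNC vectors as features. The phenotypic
#' affinity between two subjects is `s(u,v) = 1[same gender] +
#' 1[|age_u - age_v| <= ageWindow]`; with the feature kernel on, this is
#' multiplied by a correlation-distance Gaussian kernel
#' `exp(-(1 - cor(f_u, f_v))^2 / (2 sigma^2))` with `sigma` the mean
#' pairwise correlation distance. Optionally each node keeps only its
#' `kSparsify` strongest edges, symmetrized by maximum.
#'
#' @param subjects data.frame with columns `id`, `diagnosis`, `age`
#'   (months), `gender` (and any further phenotypes, carried along).
#' @param fnc n x d matrix of FNC vectors aligned with `subjects`.
#' @param ageWindow age proximity window in months.
#' @param useFeatureKernel gate phenotypic affinity by FNC similarity.
#' @param kSparsify optional per-node top-k sparsification (NULL = dense).
#' @return a [PopulationGraph-class].
#' @export
buildGraph <- function(subjects, fnc, ageWindow = 24,
                       useFeatureKernel = TRUE, kSparsify = 10L) {
  fnc <- as.matrix(fnc)
  n <- nrow(fnc)
  stopifnot(nrow(subjects) == n, ageWindow > 0)
  genderSame <- outer(as.character(subjects$gender),
                      as.character(subjects$gender), "==")
  ageClose <- abs(outer(subjects$age, subjects$age, "-")) <= ageWindow
  A <- genderSame + ageClose
  if (useFeatureKernel) {
    Dcor <- 1 - cor(t(fnc))
    sigma <- mean(Dcor[upper.tri(Dcor)])
    if (sigma <= 0) sigma <- 1
    A <- A * exp(-Dcor^2 / (2 * sigma^2))
  }
  diag(A) <- 0
  if (!is.null(kSparsify) && kSparsify < n - 1L) {
    keep <- matrix(FALSE, n, n)
    for (u in seq_len(n)) {
      ord <- order(A[u, ], decreasing = TRUE)
      keep[u, ord[seq_len(kSparsify)]] <- TRUE
    }
    keep <- keep | t(keep)       # symmetrize by maximum
    A[!keep] <- 0
  }
  if (all(A == 0))
    warning("degenerate population graph: all adjacency weights are zero")
  labels <- factor(as.character(subjects$diagnosis),
                   levels = c("control", "patient"))
  new("PopulationGraph", X = fnc, A = unname(A), labels = labels,
      ids = as.character(subjects$id),
      subjects = as.data.frame(subjects))
}

#' Population graph of a synthetic cohort
#' @param cohort cohort `SummarizedExperiment` from [generateCohort()].
#' @param ... passed to [buildGraph()].
#' @return a [PopulationGraph-class].
#' @export
cohortGraph <- function(cohort, ...) {
  buildGraph(subjectTable(cohort), fncMatrix(cohort), ...)
}

#' @rdname BiotypeGraph-generics
#' @export
setMethod("adjacency", "PopulationGraph", function(object) object@A)

#' @rdname BiotypeGraph-generics
#' @export
setMethod("nodeFeatures", "PopulationGraph", function(object) object@X)

#' @rdname BiotypeGraph-generics
#' @export
setMethod("diagnosisLabels", "PopulationGraph", function(object) object@labels)

#' @rdname BiotypeGraph-generics
#' @export
setMethod("patientMask", "PopulationGraph",
          function(object) object@labels == "patient")

#' @rdname BiotypeGraph-generics
#' @export
setMethod("subjectIds", "PopulationGraph", function(object) object@ids)

#' @rdname BiotypeGraph-generics
#' @export
setMethod("subjectTable", "PopulationGraph", function(object) object@subjects)

setMethod("show", "PopulationGraph", function(object) {
  n <- nrow(object@X)
  nE <- sum(object@A[upper.tri(object@A)] > 0)
  cat("PopulationGraph:", n, "subjects (",
      sum(object@labels == "patient"), "patients ),",
      ncol(object@X), "FNC features,", nE, "weighted edges\n")
})

#' Symmetric renormalized propagation matrix
#'
#' The standard graph-convolution propagation
#' `Ahat = D^{-1/2} (A + I) D^{-1/2}` with `D` the degree matrix of
#' `A + I`. An isolated node keeps an identity row.
#'
#' @param graph a [PopulationGraph-class] or a raw adjacency matrix.
#' @return dense symmetric propagation matrix.
#' @export
normalizeAdjacency <- function(graph) {
  A <- if (is(graph, "PopulationGraph")) adjacency(graph) else as.matrix(graph)
  if (any(A < 0)) stop("invalid adjacency: negative weights")
  Atilde <- A + diag(nrow(A))
  dInvSqrt <- 1 / sqrt(rowSums(Atilde))
  Atilde * tcrossprod(dInvSqrt)
}

#' Restrict the graph to its patient nodes
#'
#' The patient subgraph keeps patient-patient edge weights unchanged and
#' preserves node ordering; it is what the clustering layer operates on.
#'
#' @param graph a [PopulationGraph-class].
#' @return the induced [PopulationGraph-class] over patients.
#' @export
inducePatientSubgraph <- function(graph) {
  keep <- which(patientMask(graph))
  if (length(keep) == 0) stop("empty subgraph: no patients in the graph")
  new("PopulationGraph",
      X = graph@X[keep, , drop = FALSE],
      A = graph@A[keep, keep, drop = FALSE],
      labels = factor(graph@labels[keep], levels = c("control", "patient")),
      ids = graph@ids[keep],
      subjects = graph@subjects[keep, , drop = FALSE])
}

#' Restrict the graph to an arbitrary subject subset
#' @param graph a [PopulationGraph-class].
#' @param keep logical or integer index over subjects.
#' @return the induced [PopulationGraph-class].
#' @export
induceSubgraph <- function(graph, keep) {
  keep <- if (is.logical(keep)) which(keep) else as.integer(keep)
  new("PopulationGraph",
      X = graph@X[keep, , drop = FALSE],
      A = graph@A[keep, keep, drop = FALSE],
      labels = factor(graph@labels[keep], levels = c("control", "patient")),
      ids = graph@ids[keep],
      subjects = graph@subjects[keep, , drop = FALSE])
}
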