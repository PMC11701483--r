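#' @import methods
#' @importFrom stats cor dist kmeans hclust cutree rnorm runif sd var
#'   lm lm.fit pt p.adjust cor.test anova qnorm quantile setNames
#'   complete.cases median aggregate residuals as.formula
#' @importFrom utils head read.csv write.csv modifyList
NULL

#' NetworkPartition: assignment of components to functional networks
#'
#' Maps each independent-component network (ICN) to one of a small number
#' of functional networks (subcortical, auditory, sensorimotor, visual,
#' cognitive control, default mode, cerebellar in the canonical 53-component
#' layout). Used to aggregate edge-level statistics to network blocks.
#'
#' @slot labels factor of length C, one network label per component.
#' @slot networks character vector of network names, in canonical order.
#' @export
setClass("NetworkPartition",
  representation(labels = "factor", networks = "character"),
  validity = function(object) {
    msg <- NULL
    if (!all(levels(object@labels) %in% object@networks))
      msg <- c(msg, "partition labels outside the declared network set")
    if (length(object@labels) < 2L)
      msg <- c(msg, "a partition needs at least 2 components")
    if (is.null(msg)) TRUE else msg
  }
)

#' CohortSpec: parameters of the synthetic-cohort generator
#'
#' Describes a synthetic cohort with planted patient biotypes: group sizes,
#' subtype mixing proportions, the network blocks each subtype perturbs,
#' the standardized per-edge effect size, edge noise, covariate loadings,
#' and the seed that fully determines the realization.
#'
#' @slot nHC number of healthy controls.
#' @slot nPatients number of patients.
#' @slot subtypeProps mixing proportions over planted subtypes (sum 1).
#' @slot partition a [NetworkPartition-class] giving components/networks.
#' @slot effectSize standardized mean shift per affected edge (units of
#'   `noiseSd`, i.e. the planted per-edge Cohen's d).
#' @slot affectedBlocks list (one element per subtype) of two-column
#'   matrices of network-index pairs; edges inside these blocks are shifted.
#' @slot noiseSd standard deviation of the Gaussian edge noise.
#' @slot covariateSd per-edge loading scale for age/gender/site/meanFD
#'   nuisance effects.
#' @slot timepoints optional number of time points for time-course output
#'   (0 = FNC-only generation).
#' @slot fisherZ logical; generate on the Fisher-z scale and transform back.
#' @slot seed integer seed.
#' @export
setClass("CohortSpec",
  representation(
    nHC = "integer", nPatients = "integer", subtypeProps = "numeric",
    partition = "NetworkPartition", effectSize = "numeric",
    affectedBlocks = "list", noiseSd = "numeric", covariateSd = "numeric",
    timepoints = "integer", fisherZ = "logical", seed = "integer"
  ),
  validity = function(object) {
    msg <- NULL
    if (abs(sum(object@subtypeProps) - 1) > 1e-9)
      msg <- c(msg, "subtypeProps must sum to 1")
    if (any(object@subtypeProps <= 0))
      msg <- c(msg, "subtypeProps must be positive")
    if (object@effectSize < 0) msg <- c(msg, "effectSize must be >= 0")
    if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
    if (object@nPatients < length(object@subtypeProps))
      msg <- c(msg, "infeasible cohort: fewer patients than planted subtypes")
    if (length(object@affectedBlocks) != length(object@subtypeProps))
      msg <- c(msg, "affectedBlocks must have one entry per subtype")
    nNet <- length(object@partition@networks)
    for (blk in object@affectedBlocks) {
      if (!is.matrix(blk) || ncol(blk) != 2L || any(blk < 1L) || any(blk > nNet))
        msg <- c(msg, "each affectedBlocks entry must be a 2-column matrix of valid network indices")
    }
    if (is.null(msg)) TRUE else msg
  }
)

#' PopulationGraph: subjects-as-nodes graph with FNC node features
#'
#' Nodes are subjects, node features are FNC vectors, and edge weights
#' encode phenotypic (age, gender) similarity, optionally gated by an
#' FNC-similarity kernel. The adjacency carries no self-loops; these are
#' added only during propagation-matrix normalization.
#'
#' @slot X n x d node feature matrix (FNC vectors, one row per subject).
#' @slot A n x n symmetric non-negative adjacency with zero diagonal.
#' @slot labels factor with levels `control`, `patient` (diagnosis y).
#' @slot ids character subject identifiers.
#' @slot subjects data.frame of phenotypes aligned with the rows of X.
#' @export
setClass("PopulationGraph",
  representation(
    X = "matrix", A = "matrix", labels = "factor",
    ids = "character", subjects = "data.frame"
  ),
  validity = function(object) {
    msg <- NULL
    n <- nrow(object@X)
    if (nrow(object@A) != n || ncol(object@A) != n)
      msg <- c(msg, "adjacency dimensions must match the feature matrix")
    if (length(object@labels) != n || length(object@ids) != n)
      msg <- c(msg, "labels/ids must align with feature rows")
    if (n > 0 && max(abs(object@A - t(object@A))) > 1e-8)
      msg <- c(msg, "adjacency must be symmetric")
    if (n > 0 && any(diag(object@A) != 0))
      msg <- c(msg, "adjacency diagonal must be zero (self-loops are added at normalization)")
    if (n > 0 && any(object@A < 0))
      msg <- c(msg, "adjacency weights must be non-negative")
    if (!all(levels(object@labels) %in% c("control", "patient")))
      msg <- c(msg, "labels must use levels control/patient")
    if (is.null(msg)) TRUE else msg
  }
)

#' TrainingConfig: hyperparameters of the biotype model
#'
#' Loss weights follow the published setting: reconstruction weight 0.01,
#' cross-entropy weight 0.01, clustering weight 0.1, learning rate 0.001
#' (Adam). Architecture widths, epoch counts and the deep-K-means
#' inverse-temperature schedule are configurable.
#'
#' @slot gammaRec reconstruction loss weight.
#' @slot gammaCE binary cross-entropy loss weight.
#' @slot gammaCluster deep K-means loss weight.
#' @slot learningRate Adam step size.
#' @slot K number of biotypes.
#' @slot hiddenDim encoder hidden width.
#' @slot embeddingDim embedding width.
#' @slot pretrainEpochs phase-1 (reconstruction + CE) epochs.
#' @slot jointEpochs phase-2 (full objective) epochs.
#' @slot alpha0,alphaRate,alphaMax geometric annealing schedule for the
#'   soft-min inverse temperature.
#' @slot seed integer seed controlling all stochastic choices.
#' @export
setClass("TrainingConfig",
  representation(
    gammaRec = "numeric", gammaCE = "numeric", gammaCluster = "numeric",
    learningRate = "numeric", K = "integer", hiddenDim = "integer",
    embeddingDim = "integer", pretrainEpochs = "integer",
    jointEpochs = "integer", alpha0 = "numeric", alphaRate = "numeric",
    alphaMax = "numeric", seed = "integer"
  ),
  validity = function(object) {
    msg <- NULL
    if (min(object@gammaRec, object@gammaCE, object@gammaCluster) < 0)
      msg <- c(msg, "loss weights must be non-negative")
    if (object@K < 2L) msg <- c(msg, "K must be at least 2")
    if (min(object@hiddenDim, object@embeddingDim) < 1L)
      msg <- c(msg, "layer widths must be positive")
    if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
    if (object@alpha0 <= 0 || object@alphaRate < 1 || object@alphaMax < object@alpha0)
      msg <- c(msg, "annealing schedule requires alpha0 > 0, alphaRate >= 1, alphaMax >= alpha0")
    if (is.null(msg)) TRUE else msg
  }
)

#' BiotypeModel: trained biotype-discovery model
#'
#' Holds the trained encoder/decoder/classifier parameters, subject
#' embeddings, cluster centroids, patient biotype assignments (biotype 1
#' is always the largest cluster), per-biotype mean-FNC templates computed
#' from raw FNC (never from embeddings), the training configuration and
#' the per-epoch loss decomposition.
#'
#' @slot params list of weight matrices/vectors.
#' @slot embeddings n x m embedding matrix (all subjects).
#' @slot centroids K x m centroid matrix.
#' @slot assignments named integer vector of biotype labels over patients.
#' @slot templates K x d matrix of per-biotype mean FNC vectors.
#' @slot config the [TrainingConfig-class] used.
#' @slot lossHistory data.frame (epoch, phase, lRec, lCE, lCluster, total).
#' @slot ids,patientMask node bookkeeping from the training graph.
#' @export
setClass("BiotypeModel",
  representation(
    params = "list", embeddings = "matrix", centroids = "matrix",
    assignments = "integer", templates = "matrix",
    config = "TrainingConfig", lossHistory = "data.frame",
    ids = "character", patientMask = "logical"
  ),
  validity = function(object) {
    msg <- NULL
    if (length(object@assignments) != sum(object@patientMask))
      msg <- c(msg, "assignments must be defined exactly on patients")
    if (nrow(object@centroids) > 0 &&
        ncol(object@centroids) != ncol(object@embeddings))
      msg <- c(msg, "centroid and embedding widths must agree")
    if (is.null(msg)) TRUE else msg
  }
)
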