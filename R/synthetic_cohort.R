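#' Default perturbed network blocks for planted subtypes
#'
#' Subtype 1 perturbs cognitive-control/default-mode connectivity; subtype 2
#' perturbs sensorimotor-visual and visual-cerebellar connectivity, echoing
#' the network families most often implicated in attention-disorder
#' connectivity studies.
#'
#' @param nNetworks number of networks in the partition (7 canonical).
#' @return list of two 2-column matrices of network-index pairs.
#' @export
defaultAffectedBlocks <- function(nNetworks = 7L) {
  if (nNetworks >= 7L) {
    list(rbind(c(5L, 6L)),                  # CC-DM
         rbind(c(3L, 4L), c(4L, 7L)))      # SM-VI, VI-CB
  } else {
    list(rbind(c(1L, 2L)), rbind(c(1L, nNetworks)))
  }
}

#' Construct a synthetic-cohort specification
#'
#' The defaults describe the package's reference synthetic condition:
#' roughly 600 subjects (200 controls, 400 patients), two equally sized
#' planted patient subtypes expressed as network-block FNC shifts with a
#' standardized per-edge effect of 0.8 against edge noise of SD 0.1, plus
#' small age/gender/site/mean-FD covariate effects on every edge.
#'
#' @param nHC,nPatients group sizes.
#' @param subtypeProps mixing proportions over planted subtypes.
#' @param partition a [NetworkPartition-class]; defaults to the 53-component
#'   7-network layout.
#' @param effectSize standardized per-edge mean shift (units of `noiseSd`).
#' @param affectedBlocks per-subtype list of network-pair matrices.
#' @param noiseSd Gaussian edge-noise SD.
#' @param covariateSd per-edge covariate loading scale.
#' @param timepoints if > 0, time courses of this length can be generated.
#' @param fisherZ generate on the Fisher-z scale (tanh-transformed back).
#' @param seed integer seed; fully determines the cohort.
#' @return a [CohortSpec-class] object.
#' @export
cohortSpec <- function(nHC = 200L, nPatients = 400L,
                       subtypeProps = c(0.5, 0.5),
                       partition = networkPartition(),
                       effectSize = 0.8,
                       affectedBlocks = defaultAffectedBlocks(length(partition@networks)),
                       noiseSd = 0.1, covariateSd = 0.005,
                       timepoints = 0L, fisherZ = FALSE, seed = 1L) {
  new("CohortSpec",
      nHC = as.integer(nHC), nPatients = as.integer(nPatients),
      subtypeProps = subtypeProps, partition = partition,
      effectSize = effectSize, affectedBlocks = lapply(affectedBlocks, function(b) {
        b <- as.matrix(b); storage.mode(b) <- "integer"; b
      }),
      noiseSd = noiseSd, covariateSd = covariateSd,
      timepoints = as.integer(timepoints), fisherZ = fisherZ,
      seed = as.integer(seed))
}

#' Logical mask of edges lying inside a set of network blocks
#' @param partition a [NetworkPartition-class].
#' @param blocks 2-column matrix of network-index pairs (unordered).
#' @return logical vector over the canonical edge index.
#' @export
blockEdgeMask <- function(partition, blocks) {
  C <- componentCount(partition)
  idx <- edgeIndex(C)
  neti <- as.integer(partition@labels[idx$i])
  netj <- as.integer(partition@labels[idx$j])
  mask <- rep(FALSE, nrow(idx))
  for (r in seq_len(nrow(blocks))) {
    a <- blocks[r, 1L]; b <- blocks[r, 2L]
    mask <- mask | (neti == a & netj == b) | (neti == b & netj == a)
  }
  mask
}

#' Generate a synthetic cohort with planted biotype structure
#'
#' Every subject's FNC vector is a shared base connectivity pattern plus
#' covariate effects plus Gaussian edge noise; patients additionally
#' receive their subtype's block shift (`effectSize * noiseSd` at every
#' edge inside the subtype's affected network blocks). Edge values are
#' clipped to the open interval (-1, 1). The same spec (same seed)
#' regenerates the cohort bit-identically.
#'
#' @param spec a [CohortSpec-class].
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `fnc` (edges x subjects), subject phenotypes in `colData`
#'   (diagnosis, hidden `trueSubtype`, age in months, gender, site,
#'   meanFD, cognition and symptom scores) and the spec in `metadata`.
#' @examples
#' co <- generateCohort(cohortSpec(nHC = 10, nPatients = 20, seed = 1))
#' dim(fncMatrix(co))  # 30 x 1378
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  part <- spec@partition
  C <- componentCount(part)
  idx <- edgeIndex(C)
  d <- nrow(idx)
  K <- length(spec@subtypeProps)
  n <- spec@nHC + spec@nPatients

  # population-level structure (shared base connectivity and covariate
  # loadings) is drawn from a fixed stream so that independently seeded
  # cohorts describe the same underlying population, as two sites
  # scanning the same disorder would; the cohort seed governs subjects,
  # noise and covariate values only
  set.seed(20090L)
  base <- pmin(pmax(rnorm(d, mean = 0.15, sd = 0.1), -0.6), 0.6)
  loadings <- matrix(rnorm(4L * d, 0, spec@covariateSd), nrow = 4L)

  set.seed(spec@seed)

  # subtype block shifts (standardized effect in units of the noise SD)
  shift <- matrix(0, nrow = K, ncol = d)
  for (k in seq_len(K))
    shift[k, blockEdgeMask(part, spec@affectedBlocks[[k]])] <-
      spec@effectSize * spec@noiseSd

  # deterministic largest-remainder subtype counts, then randomized order
  raw <- spec@subtypeProps * spec@nPatients
  cnt <- floor(raw)
  rem <- spec@nPatients - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1L
  }
  subtype <- sample(rep.int(seq_len(K), cnt))

  diagnosis <- factor(rep(c("control", "patient"), c(spec@nHC, spec@nPatients)),
                      levels = c("control", "patient"))
  trueSubtype <- c(rep(NA_integer_, spec@nHC), subtype)
  age <- round(rnorm(n, mean = 119, sd = 7.5))
  age[age < 72] <- 72L
  gender <- factor(sample(c("M", "F"), n, replace = TRUE, prob = c(0.6, 0.4)),
                   levels = c("M", "F"))
  site <- factor(sample(c("siteA", "siteB"), n, replace = TRUE),
                 levels = c("siteA", "siteB"))
  meanFD <- pmax(rnorm(n, mean = 0.15, sd = 0.05), 0.02)

  # covariate design (age, gender, site, meanFD), standardized
  covZ <- cbind(as.numeric(scale(age)),
                as.numeric(gender == "M") - mean(gender == "M"),
                as.numeric(site == "siteB") - mean(site == "siteB"),
                as.numeric(scale(meanFD)))

  means <- matrix(base, nrow = n, ncol = d, byrow = TRUE) + covZ %*% loadings
  pat <- which(diagnosis == "patient")
  means[pat, ] <- means[pat, ] + shift[subtype, , drop = FALSE]

  fnc <- means + matrix(rnorm(n * d, 0, spec@noiseSd), nrow = n)
  if (spec@fisherZ) fnc <- tanh(fnc) else
    fnc <- pmin(pmax(fnc, -1 + 1e-8), 1 - 1e-8)

  # phenotype scores: subtype 2 planted as the more severe / lower-cognition
  isPat <- as.numeric(diagnosis == "patient")
  sev <- ifelse(is.na(trueSubtype), 0, as.numeric(trueSubtype == K))
  cognition <- 100 - 6 * isPat - 4 * sev + rnorm(n, 0, 10)
  symptom <- 18 + 25 * isPat + 4 * sev + rnorm(n, 0, 5)

  ids <- sprintf("sub%04d", seq_len(n))
  dimnames(fnc) <- list(ids, idx$edge)

  SummarizedExperiment::SummarizedExperiment(
    assays = list(fnc = t(fnc)),
    rowData = S4Vectors::DataFrame(idx),
    colData = S4Vectors::DataFrame(
      id = ids, diagnosis = diagnosis, trueSubtype = trueSubtype,
      age = age, gender = gender, site = site, meanFD = meanFD,
      cognition = cognition, symptom = symptom, row.names = ids),
    metadata = list(spec = spec)
  )
}

#' Subjects-by-edges FNC matrix of a cohort
#' @param cohort a cohort `SummarizedExperiment` from [generateCohort()].
#' @return n x d numeric matrix (subjects in rows).
#' @export
fncMatrix <- function(cohort) t(SummarizedExperiment::assay(cohort, "fnc"))

#' @rdname BiotypeGraph-generics
#' @export
setMethod("subjectTable", "SummarizedExperiment",
          function(object) as.data.frame(SummarizedExperiment::colData(object)))

#' Nearest positive semi-definite correlation repair
#'
#' Floors the eigenvalues of a symmetric matrix at `floorAt` and rescales
#' back to unit diagonal.
#'
#' @param mat symmetric matrix.
#' @param floorAt eigenvalue floor.
#' @return repaired correlation matrix.
#' @export
nearestPSD <- function(mat, floorAt = 1e-6) {
  mat <- (mat + t(mat)) / 2
  e <- eigen(mat, symmetric = TRUE)
  vals <- pmax(e$values, floorAt)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- (out + t(out)) / 2
  stats::cov2cor(out)
}

#' Sample component time courses with a target correlation structure
#'
#' Draws Gaussian time courses whose empirical Pearson correlation
#' converges to the target matrix as T grows; the target is repaired to
#' the nearest positive semi-definite correlation first.
#'
#' @param targetFNC either an upper-triangle FNC vector or a C x C
#'   symmetric correlation matrix.
#' @param timepoints number of samples T (must be >= C).
#' @param seed integer seed.
#' @return C x T matrix with zero-mean, unit-variance rows.
#' @export
generateTimecourses <- function(targetFNC, timepoints, seed = 1L) {
  target <- if (is.matrix(targetFNC)) targetFNC else unvectorizeFNC(targetFNC)
  C <- nrow(target)
  if (timepoints < C)
    stop("ill-conditioned sample: need T >= ", C, " time points, got ", timepoints)
  R <- nearestPSD(target)
  L <- t(chol(R))
  set.seed(seed)
  Z <- matrix(rnorm(C * timepoints), nrow = C)
  X <- L %*% Z
  # standardize rows; Pearson correlation is invariant to this
  X <- t(scale(t(X)))
  dimnames(X) <- NULL
  X
}

#' Default per-(biotype, arm) weekly recovery slopes
#'
#' Points of symptom reduction per week: biotype 1 responds faster to the
#' stimulant (MPH), biotype 2 to the non-stimulant (ATX).
#' @param K number of biotypes.
#' @return K x 2 matrix with columns MPH, ATX.
#' @export
defaultEffectPlan <- function(K = 2L) {
  plan <- matrix(2.25, nrow = K, ncol = 2,
                 dimnames = list(as.character(seq_len(K)), c("MPH", "ATX")))
  if (K >= 2) {
    plan[1, ] <- c(3.0, 1.5)
    plan[2, ] <- c(1.5, 3.0)
  }
  plan
}

#' Generate longitudinal symptom trajectories under treatment
#'
#' Scores follow `baseline - slope(biotype, arm) * week` plus a
#' subject-specific random intercept and slope and observation noise,
#' floored at zero. Weeks include the baseline visit (0).
#'
#' @param subjects data.frame with columns `id` and `biotype`; an optional
#'   `med` column fixes the arm, otherwise arms are randomized.
#' @param weeks visit weeks; must include 0.
#' @param effectPlan K x 2 slope matrix (columns MPH, ATX), points/week.
#' @param baselineMean,baselineSd distribution of the week-0 scale score.
#' @param reInterceptSd,reSlopeSd random-effect SDs.
#' @param noiseSd observation noise SD.
#' @param scale scale name recorded on each row.
#' @param probMPH probability of the MPH arm when randomizing.
#' @param seed integer seed.
#' @return long-format data.frame (id, biotype, med, week, scale, score).
#' @export
generateLongitudinal <- function(subjects, weeks = c(0, 1, 2, 3, 4, 8),
                                 effectPlan = defaultEffectPlan(),
                                 baselineMean = 40, baselineSd = 5,
                                 reInterceptSd = 3, reSlopeSd = 0.3,
                                 noiseSd = 2, scale = "RS-Total",
                                 probMPH = 27 / 44, seed = 1L) {
  if (!all(c("id", "biotype") %in% names(subjects)))
    stop("subjects needs columns 'id' and 'biotype'")
  if (any(is.na(subjects$biotype)))
    stop("missing biotype assignment for subject(s): ",
         paste(subjects$id[is.na(subjects$biotype)], collapse = ", "))
  if (!0 %in% weeks) stop("weeks must include the baseline visit (0)")
  set.seed(seed)
  ns <- nrow(subjects)
  med <- if ("med" %in% names(subjects)) as.character(subjects$med) else
    sample(c("MPH", "ATX"), ns, replace = TRUE, prob = c(probMPH, 1 - probMPH))
  if (!all(med %in% colnames(effectPlan)))
    stop("every medicated subject needs an arm among: ",
         paste(colnames(effectPlan), collapse = ", "))
  baseline <- rnorm(ns, baselineMean, baselineSd)
  b0 <- rnorm(ns, 0, reInterceptSd)
  b1 <- rnorm(ns, 0, reSlopeSd)
  slope <- effectPlan[cbind(as.character(subjects$biotype), med)]
  out <- do.call(rbind, lapply(seq_len(ns), function(s) {
    sc <- baseline[s] - slope[s] * weeks + b0[s] + b1[s] * weeks +
      rnorm(length(weeks), 0, noiseSd)
    data.frame(id = subjects$id[s], biotype = subjects$biotype[s],
               med = med[s], week = weeks, scale = scale,
               score = pmax(sc, 0), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
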