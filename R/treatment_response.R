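#' Reduction rates with baseline adjustment
#'
#' Adds `reductionRate = (baseline - score) / baseline` per id x scale
#' (0 at the baseline visit by construction) and `adjustedReduction`, the
#' cross-sectional residual of the reduction rate on the baseline score
#' at each week (the "baseline regressed out" convention).
#'
#' @param records long data.frame (id, week, scale, score, ...); week 0
#'   must be present for every id x scale with a positive score.
#' @return the records with `reductionRate` and `adjustedReduction`.
#' @export
computeReduction <- function(records) {
  need <- c("id", "week", "scale", "score")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  key <- interaction(records$id, records$scale, drop = TRUE)
  base <- records$score[records$week == 0][match(key, key[records$week == 0])]
  if (anyNA(base))
    stop("missing baseline (week 0) for some id x scale")
  if (any(base == 0)) {
    bad <- unique(records$id[base == 0])
    stop("undefined reduction: zero baseline for id(s) ",
         paste(bad, collapse = ", "))
  }
  records$baseline <- base
  records$reductionRate <- (base - records$score) / base
  records$adjustedReduction <- NA_real_
  for (sc in unique(records$scale)) for (w in unique(records$week)) {
    sel <- records$scale == sc & records$week == w
    if (sum(sel) >= 2 && sd(records$baseline[sel]) > 0) {
      fit <- lm(reductionRate ~ baseline, data = records[sel, ])
      records$adjustedReduction[sel] <- residuals(fit)
    } else {
      records$adjustedReduction[sel] <-
        records$reductionRate[sel] - mean(records$reductionRate[sel])
    }
  }
  records
}

#' Fit the longitudinal interaction mixed model
#'
#' Two specifications, both with a subject random intercept and (by
#' default) a random week slope, tested by ANOVA F-tests (Satterthwaite
#' degrees of freedom via lmerTest) at the conventional alpha = 0.05:
#' * `week_by_biotype`: `response ~ week * biotype + (1 + week | id)` on
#'   post-baseline reduction rates;
#' * `full`: `response ~ week * biotype + med * biotype + week * med +
#'   (1 + week | id)` — the biotype-by-medication specification.
#'
#' A singular random-slope fit falls back to a random-intercept-only
#' model, recorded in the `note` column.
#'
#' @param records long data.frame with columns id, week, biotype, med
#'   (for the full model), and the response.
#' @param response column name of the dependent variable.
#' @param model which fixed-effect specification to fit.
#' @param weekAsFactor treat week as categorical instead of numeric.
#' @param randomSlope include the per-subject week slope.
#' @return data.frame (term, F, df1, df2, p, note).
#' @export
fitInteractionModel <- function(records,
                                response = "reductionRate",
                                model = c("week_by_biotype", "full"),
                                weekAsFactor = FALSE,
                                randomSlope = TRUE) {
  model <- match.arg(model)
  dat <- as.data.frame(records)
  dat$.y <- dat[[response]]
  dat$biotype <- factor(dat$biotype)
  if (model == "full") dat$med <- factor(dat$med)
  dat$.week <- if (weekAsFactor) factor(dat$week) else as.numeric(dat$week)
  if (length(unique(dat$id)) < 2) stop("grouping factor needs >= 2 subjects")
  fixed <- if (model == "week_by_biotype") ".y ~ .week * biotype" else
    ".y ~ .week * biotype + med * biotype + .week * med"
  note <- ""
  fitOne <- function(ranef) {
    lmerTest::lmer(as.formula(paste(fixed, "+", ranef)), data = dat,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore"))
  }
  fit <- NULL
  if (randomSlope && !weekAsFactor) {
    fit <- tryCatch(suppressWarnings(suppressMessages(
      fitOne("(1 + .week | id)"))), error = function(e) NULL)
    if (!is.null(fit) && lme4::isSingular(fit, tol = 1e-4)) {
      note <- "singular random slope; refit with random intercept only"
      fit <- NULL
    }
  }
  if (is.null(fit)) {
    if (note == "") note <- if (randomSlope && !weekAsFactor)
      "random-slope fit failed; random intercept only" else ""
    fit <- suppressWarnings(suppressMessages(fitOne("(1 | id)")))
  }
  av <- suppressWarnings(anova(fit))  # lmerTest: Satterthwaite F tests
  out <- data.frame(term = gsub("\\.week", "week", rownames(av)),
                    F = av$`F value`, df1 = av$NumDF, df2 = av$DenDF,
                    p = av$`Pr(>F)`, note = note,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulation harness for mixed-model calibration and power
#'
#' Repeatedly generates longitudinal cohorts with [generateLongitudinal()]
#' and fits [fitInteractionModel()], returning the per-simulation p-value
#' of one model term. Used for type-I-error checks (all slopes equal,
#' `week:biotype` term) and power checks (planted biotype-by-medication
#' slope difference, `biotype:med` term).
#'
#' @param nSims number of simulated cohorts.
#' @param nSubjects subjects per cohort.
#' @param effectPlan K x 2 slope matrix passed to the generator.
#' @param term which model term's p-value to collect.
#' @param model model specification to fit.
#' @param response response column ("reductionRate", "adjustedReduction"
#'   or "score").
#' @param seed base seed; simulation s uses `seed + s`.
#' @param ... further arguments to [generateLongitudinal()].
#' @return numeric vector of p-values (NA for failed fits).
#' @export
simulateTreatmentPvalues <- function(nSims, nSubjects = 44L,
                                     effectPlan = defaultEffectPlan(),
                                     term = "week:biotype",
                                     model = "week_by_biotype",
                                     response = "reductionRate",
                                     seed = 1L, ...) {
  vapply(seq_len(nSims), function(s) {
    set.seed(seed + s)
    subj <- data.frame(id = sprintf("s%03d", seq_len(nSubjects)),
                       biotype = sample(rep_len(1:2, nSubjects)))
    long <- generateLongitudinal(subj, effectPlan = effectPlan,
                                 seed = seed + s, ...)
    long <- computeReduction(long)
    dat <- if (response == "score") long else long[long$week > 0, ]
    res <- tryCatch(
      fitInteractionModel(dat, response = response, model = model),
      error = function(e) NULL)
    if (is.null(res) || !term %in% res$term) return(NA_real_)
    res$p[res$term == term]
  }, numeric(1))
}
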