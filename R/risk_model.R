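# Prognostic risk modelling: a LASSO-penalized Cox model over subtype
# signature genes yields a linear overall survival score (OSS); the
# training-median OSS stratifies samples into high- and low-risk groups
# whose survival is compared by the log-rank test.

#' The published ten-gene overall survival score
#'
#' Returns the ten-gene OSS model exactly as printed:
#' OSS = 0.0166 MFAP4 + 0.1858 FBLN2 + 0.0227 IGF2 - 0.0034 NME5
#'       - 0.1435 MGLL - 0.0101 COLEC11 - 0.0415 AGR2 - 0.0453 TFF3
#'       - 0.0199 PAEP - 0.0275 DEFB1.
#' Three genes (from the poor-prognosis subtype signature) carry positive
#' risk coefficients and seven (from the good-prognosis subtype) negative
#' protective ones. The stratification cut-point is not part of the
#' printed model and is left NA.
#'
#' @return a [RiskModel-class] with provenance `"published"`.
#' @examples
#' m <- publishedModel()
#' sum(riskCoefficients(m))  # -0.0661
#' @export
publishedModel <- function() {
  coefs <- c(MFAP4 = 0.0166, FBLN2 = 0.1858, IGF2 = 0.0227,
             NME5 = -0.0034, MGLL = -0.1435, COLEC11 = -0.0101,
             AGR2 = -0.0415, TFF3 = -0.0453, PAEP = -0.0199,
             DEFB1 = -0.0275)
  new("RiskModel", genes = names(coefs), coefficients = coefs,
      cutpoint = NA_real_, provenance = "published")
}

#' Fit a LASSO-Cox risk model
#'
#' L1-penalized Cox partial likelihood over the candidate genes with the
#' penalty chosen by cross-validated partial-likelihood deviance (1-SE
#' rule by default). Genes with nonzero coefficients at the chosen
#' penalty form the model; the training cut-point is the median OSS of
#' the training samples.
#'
#' @param E expression container or genes-by-samples matrix.
#' @param survival data.frame with columns `sample`, `time` (> 0),
#'   `event` (0/1); or taken from `colData(E)` columns `time`/`event`.
#' @param candidates candidate gene names (must be present in `E`).
#' @param cv_folds cross-validation folds (default 10).
#' @param seed RNG seed controlling the fold split.
#' @param lambda `"1se"` (default), `"min"`, or a numeric penalty
#'   override.
#' @param min_samples,min_events guard rails on the training set
#'   (defaults 30 and 10).
#' @return a [RiskModel-class] with provenance `"fitted"`.
#' @export
fitLassoCox <- function(E, survival = NULL, candidates, cv_folds = 10,
                        seed = 1L, lambda = "1se", min_samples = 30,
                        min_events = 10) {
  if (is(E, "SummarizedExperiment") && is.null(survival)) {
    cd <- colData(E)
    survival <- data.frame(sample = rownames(cd), time = cd$time,
                           event = cd$event, stringsAsFactors = FALSE)
  }
  M <- exprsOf(E)
  missing <- setdiff(candidates, rownames(M))
  if (length(missing))
    stop("candidate genes absent from matrix: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  survival <- survival[complete.cases(survival[, c("time", "event")]), ,
                       drop = FALSE]
  survival <- survival[survival$sample %in% colnames(M), , drop = FALSE]
  validateSurvival(survival)
  if (nrow(survival) < min_samples)
    stop("need at least ", min_samples, " samples with survival",
         call. = FALSE)
  if (sum(survival$event) < min_events)
    stop("need at least ", min_events, " events", call. = FALSE)
  X <- t(M[candidates, survival$sample, drop = FALSE])
  y <- survival::Surv(survival$time, survival$event)
  foldid <- withSeed(seed, sample(rep(seq_len(cv_folds),
                                      length.out = nrow(X))))
  cv <- glmnet::cv.glmnet(X, y, family = "cox", alpha = 1,
                          foldid = foldid, standardize = TRUE)
  lam <- if (identical(lambda, "1se")) cv$lambda.1se
  else if (identical(lambda, "min")) cv$lambda.min
  else as.numeric(lambda)
  beta <- as.matrix(stats::coef(cv$glmnet.fit, s = lam))[, 1]
  beta <- beta[beta != 0]
  if (length(beta) == 0)
    stop("all coefficients are zero at the chosen penalty; ",
         "try lambda = 'min' or a smaller numeric penalty",
         call. = FALSE)
  model <- new("RiskModel", genes = names(beta), coefficients = beta,
               cutpoint = NA_real_, provenance = "fitted")
  model@cutpoint <- median(ossScore(model, M[, survival$sample,
                                             drop = FALSE]))
  model
}

#' Overall survival score
#'
#' OSS(sample) = sum over model genes of coefficient times expression.
#'
#' @param model a [RiskModel-class].
#' @param E expression container or genes-by-samples matrix containing
#'   every model gene (no silent imputation).
#' @return named numeric vector of per-sample scores.
#' @export
ossScore <- function(model, E) {
  stopifnot(is(model, "RiskModel"))
  M <- exprsOf(E)
  missing <- setdiff(model@genes, rownames(M))
  if (length(missing))
    stop("model genes absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  drop(crossprod(M[model@genes, , drop = FALSE], model@coefficients))
}

#' Stratify samples into high- and low-risk groups
#'
#' @param scores named OSS values.
#' @param cutpoint threshold; high risk iff score > cutpoint. A
#'   [RiskModel-class] may be supplied to use its training cut-point.
#' @return factor with levels `low`, `high`, named by sample.
#' @export
stratify <- function(scores, cutpoint) {
  if (is(cutpoint, "RiskModel")) cutpoint <- riskCutpoint(cutpoint)
  if (is.na(cutpoint)) stop("no cut-point available", call. = FALSE)
  g <- factor(ifelse(scores > cutpoint, "high", "low"),
              levels = c("low", "high"))
  names(g) <- names(scores)
  if (length(unique(g[!is.na(g)])) < 2)
    warning("all samples fall in a single risk group")
  g
}

validateSurvival <- function(survival) {
  if (!all(c("sample", "time", "event") %in% colnames(survival)))
    stop("survival table needs columns sample, time, event",
         call. = FALSE)
  if (any(survival$time <= 0))
    stop("survival times must be positive", call. = FALSE)
  if (!all(survival$event %in% c(0, 1)))
    stop("event must be 0 or 1", call. = FALSE)
  invisible(survival)
}

#' Two-group log-rank test
#'
#' The standard log-rank statistic (observed minus expected events in one
#' group, summed over event times, normalized by the hypergeometric
#' variance of the risk-set table), referred to chi-square with 1 degree
#' of freedom.
#'
#' @param groups named two-level factor over samples.
#' @param survival data.frame with columns `sample`, `time`, `event`.
#' @return list with `statistic` (chi-square) and `p`.
#' @export
logrankTest <- function(groups, survival) {
  validateSurvival(survival)
  groups <- groups[!is.na(groups)]
  keep <- intersect(names(groups), survival$sample)
  survival <- survival[match(keep, survival$sample), , drop = FALSE]
  g <- droplevels(factor(groups[keep]))
  if (nlevels(g) != 2)
    stop("need exactly two nonempty groups", call. = FALSE)
  fit <- survival::survdiff(
    survival::Surv(time, event) ~ g,
    data = data.frame(time = survival$time, event = survival$event,
                      g = g))
  stat <- fit$chisq
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}
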