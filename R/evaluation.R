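aucEstimate <- function(scores, truth) {
  cpp_auc(as.numeric(scores), as.logical(truth))
}

rocCurvePoints <- function(scores, truth) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  n1 <- sum(truth); n0 <- length(truth) - n1
  last <- c(s[-1] != s[-length(s)], TRUE)  # end of each tie group
  tp <- cumsum(t)[last]; fp <- cumsum(!t)[last]
  data.frame(fpr = c(0, fp / n0), tpr = c(0, tp / n1),
             threshold = c(Inf, s[last]))
}

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney concordance probability (ties counted 1/2); the
#' ROC curve is traced over all score thresholds.
#'
#' @param scores numeric per-patient scores (e.g. predicted invasive
#'   probability).
#' @param truth logical (or 0/1) outcome, `TRUE` = positive class.
#' @param stratum optional label recorded in the report.
#' @return A [RocReport-class] without confidence interval.
#' @examples
#' rocAuc(c(0.9, 0.8, 0.3, 0.2), c(TRUE, FALSE, TRUE, FALSE))  # AUC 0.75
#' @export
rocAuc <- function(scores, truth, stratum = "") {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), !anyNA(scores), !anyNA(truth))
  if (length(unique(truth)) < 2L)
    stop("both outcome classes must be present")
  new("RocReport", auc = aucEstimate(scores, truth),
      ciLow = NA_real_, ciHigh = NA_real_, level = NA_real_, nBootstrap = 0,
      rocPoints = rocCurvePoints(scores, truth), replicates = numeric(),
      stratum = stratum, seed = NA_real_)
}

stratifiedBootAuc <- function(scores, truth, nBootstrap) {
  pos <- which(truth); neg <- which(!truth)
  n1 <- length(pos); n0 <- length(neg)
  vapply(seq_len(nBootstrap), function(b) {
    idx <- c(pos[sample.int(n1, n1, replace = TRUE)],
             neg[sample.int(n0, n0, replace = TRUE)])
    aucEstimate(scores[idx], truth[idx])
  }, numeric(1))
}

#' Patient-stratified percentile-bootstrap confidence interval for the AUC
#'
#' Patients are resampled with replacement within each outcome class (so
#' every replicate keeps the observed case/control counts), the AUC is
#' recomputed per replicate, and the confidence limits are percentile order
#' statistics of the replicate AUCs. Deterministic given `seed`.
#'
#' @inheritParams rocAuc
#' @param nBootstrap number of bootstrap replicates (at least 100; default
#'   2000).
#' @param level confidence level in (0, 1).
#' @param seed integer RNG seed.
#' @return A [RocReport-class] with CI and stored replicates.
#' @export
bootstrapAucCi <- function(scores, truth, nBootstrap = 2000, level = 0.95,
                           seed = 1, stratum = "") {
  truth <- as.logical(truth)
  if (length(unique(truth)) < 2L)
    stop("both outcome classes must be present")
  if (nBootstrap < 100) stop("nBootstrap must be at least 100")
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("level must lie in (0, 1)")
  reps <- withSeed(seed, stratifiedBootAuc(scores, truth, nBootstrap))
  alpha <- 1 - level
  ci <- quantile(reps, c(alpha / 2, 1 - alpha / 2), type = 1, names = FALSE)
  new("RocReport", auc = aucEstimate(scores, truth),
      ciLow = ci[1], ciHigh = ci[2], level = level, nBootstrap = nBootstrap,
      rocPoints = rocCurvePoints(scores, truth), replicates = reps,
      stratum = stratum, seed = seed)
}

#' Bootstrap comparison of two AUCs from independent patient sets
#'
#' For two classifiers evaluated on disjoint patient sets (e.g. the high and
#' low density strata), each replicate resamples both datasets
#' class-stratified and records the AUC difference. The test statistic is
#' D = (AUC_a - AUC_b) / sd(bootstrap differences), referred to the standard
#' normal law (two-sided) - the unpaired bootstrap scheme popularized by the
#' pROC package.
#'
#' @param scoresA,truthA scores and outcomes of the first dataset.
#' @param scoresB,truthB scores and outcomes of the second dataset.
#' @param nBootstrap number of replicates (at least 100; default 2000).
#' @param seed integer RNG seed.
#' @return An [AucComparison-class].
#' @export
compareAucBootstrap <- function(scoresA, truthA, scoresB, truthB,
                                nBootstrap = 2000, seed = 1) {
  truthA <- as.logical(truthA); truthB <- as.logical(truthB)
  if (nBootstrap < 100) stop("nBootstrap must be at least 100")
  aucA <- aucEstimate(scoresA, truthA)
  aucB <- aucEstimate(scoresB, truthB)
  diffs <- withSeed(seed, {
    repsA <- stratifiedBootAuc(scoresA, truthA, nBootstrap)
    repsB <- stratifiedBootAuc(scoresB, truthB, nBootstrap)
    repsA - repsB
  })
  s <- sd(diffs)
  d <- aucA - aucB
  if (s > 0) {
    stat <- d / s
    p <- 2 * pnorm(-abs(stat))
  } else {
    stat <- if (d == 0) 0 else sign(d) * Inf
    p <- if (d == 0) 1 else 0
  }
  new("AucComparison", aucA = aucA, aucB = aucB, statistic = stat,
      pValue = p, nBootstrap = nBootstrap, seed = seed)
}
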