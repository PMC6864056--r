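#' Assemble the patient-level cohort table
#'
#' Joins patient-level features with patient metadata (density targets,
#' diagnosis, split, covariates). When the metadata carries several rows per
#' patient (one per biopsy/slide), the diagnosis is collapsed to the worst
#' across biopsies and the first value of the remaining columns is used.
#'
#' @param patientFeatures data.frame from [aggregateCohort()].
#' @param metadata slide-level metadata (as from [generateCohort()]).
#' @return data.frame with one row per patient: features, `global_fgv`,
#'   `localized_fgv`, `diagnosis`, `split`, `bmi`, `menopause`.
#' @export
buildCohortTable <- function(patientFeatures, metadata) {
  pieces <- split(metadata, metadata$patient_id)
  meta <- do.call(rbind, lapply(pieces, function(d) {
    data.frame(patient_id = d$patient_id[1],
               split = d$split[1],
               diagnosis = worstDiagnosis(d$diagnosis),
               global_fgv = d$global_fgv[1],
               localized_fgv = d$localized_fgv[1],
               bmi = d$bmi[1], menopause = d$menopause[1])
  }))
  out <- merge(meta, patientFeatures, by = "patient_id", sort = TRUE)
  rownames(out) <- NULL
  out
}

rankImportance <- function(imp) {
  ord <- order(-imp)  # stable: ties keep canonical column order
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             rank = seq_along(imp))
}

#' Random-forest regression of fibroglandular volume
#'
#' Fits a random-forest regressor of a percent fibroglandular-volume target
#' on the feature columns, using the training split only, and ranks all
#' input features by impurity-based (Gini/node-purity) importance.
#' Deterministic given `seed`.
#'
#' @param cohort patient-level table from [buildCohortTable()].
#' @param target `"global_fgv"` or `"localized_fgv"`.
#' @param features feature columns to use (default the canonical 37).
#' @param covariates optional extra covariate columns (e.g. `"bmi"`) for
#'   sensitivity analyses; an empty set leaves the feature-only model
#'   untouched.
#' @param ntree,mtry forest size and per-split feature sample
#'   (defaults: 500 trees, p/3).
#' @param seed integer RNG seed.
#' @return list with elements `model` (the randomForest fit), `ranking`
#'   (data.frame `feature`, `importance`, `rank`), `target`, `featureSet`,
#'   `seed`.
#' @export
trainFgvRegressor <- function(cohort, target = "global_fgv",
                              features = featureNames(),
                              covariates = character(), ntree = 500,
                              mtry = NULL, seed = 1) {
  if (!target %in% names(cohort))
    stop("target column '", target, "' not found in cohort table")
  train <- cohort[cohort$split == "train", , drop = FALSE]
  if (nrow(train) == 0L) stop("training split is empty")
  featureSet <- c(features, covariates)
  x <- train[, featureSet, drop = FALSE]
  if (anyNA(x)) stop("feature columns must be complete")
  y <- train[[target]]
  if (is.null(mtry)) mtry <- max(floor(length(featureSet) / 3), 1)
  fit <- withSeed(seed,
    randomForest::randomForest(x = x, y = y, ntree = ntree, mtry = mtry))
  imp <- fit$importance[, "IncNodePurity"]
  list(model = fit, ranking = rankImportance(imp), target = target,
       featureSet = featureSet, seed = seed)
}

#' Predicted-vs-actual Spearman correlation on the held-out split
#'
#' @param fit result of [trainFgvRegressor()].
#' @param cohort patient-level cohort table containing a test split.
#' @param target target column (defaults to the one the model was fit on).
#' @return list with `spearman` (rank correlation between predicted and
#'   actual target over test patients) and `predictions` (data.frame
#'   `patient_id`, `predicted`, `actual`).
#' @export
predictAndCorrelate <- function(fit, cohort, target = fit$target) {
  test <- cohort[cohort$split == "test", , drop = FALSE]
  if (nrow(test) < 3L) stop("need at least 3 test patients")
  pred <- predict(fit$model, newdata = test[, fit$featureSet, drop = FALSE])
  actual <- test[[target]]
  list(spearman = cor(pred, actual, method = "spearman"),
       predictions = data.frame(patient_id = test$patient_id,
                                predicted = as.numeric(pred),
                                actual = actual))
}

#' Prune highly correlated features
#'
#' Walks feature pairs in canonical column order; whenever both members of a
#' pair with absolute Spearman correlation at or above the threshold are
#' still retained, one of the two is removed, chosen by the seeded RNG.
#' Deterministic given `seed`.
#'
#' @param x data.frame or matrix of feature columns (observations in rows);
#'   typically the training split only.
#' @param threshold correlation threshold in (0, 1] (default 0.85).
#' @param seed integer RNG seed.
#' @return character vector of retained feature names, in column order.
#' @export
pruneCorrelated <- function(x, threshold = 0.85, seed = 1) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  x <- as.data.frame(x)
  if (ncol(x) < 2L) stop("need at least 2 features")
  rho <- suppressWarnings(cor(x, method = "spearman"))
  rho[is.na(rho)] <- 0  # constant columns correlate with nothing
  p <- ncol(x)
  retained <- rep(TRUE, p)
  withSeed(seed, {
    for (i in seq_len(p - 1L)) {
      if (!retained[i]) next
      for (j in seq.int(i + 1L, p)) {
        if (retained[i] && retained[j] && abs(rho[i, j]) >= threshold)
          retained[sample(c(i, j), 1L)] <- FALSE
      }
    }
  })
  colnames(x)[retained]
}

#' Stratify patients at the training-split median of a density target
#'
#' The cutpoint is the median of the target over training patients; all
#' patients (both splits) with target strictly above it form the high
#' stratum, ties and below the low stratum.
#'
#' @param cohort patient-level cohort table.
#' @param target `"global_fgv"` or `"localized_fgv"`.
#' @return list with `cutpoint` and `stratum` (character vector aligned with
#'   the cohort rows, `"high"`/`"low"`).
#' @export
stratifyByMedian <- function(cohort, target = "global_fgv") {
  train <- cohort[cohort$split == "train", , drop = FALSE]
  if (nrow(train) == 0L) stop("training split is empty")
  cut <- median(train[[target]])
  list(cutpoint = cut,
       stratum = ifelse(cohort[[target]] > cut, "high", "low"))
}

degenerateStratumError <- function(detail) {
  errorCondition(paste0("degenerate stratum: ", detail),
                 class = c("degenerateStratumError", "error", "condition"))
}

#' Random-forest invasive-vs-benign classifier within a stratum
#'
#' Binary outcome: invasive carcinoma versus benign breast disease
#' (non-proliferative and proliferative with or without atypia). In-situ
#' diagnoses are excluded from both training and testing before anything is
#' fit. Trains on the stratum's training patients, scores its test patients
#' with predicted invasive probabilities, and ranks features by mean Gini
#' decrease. Deterministic given `seed`.
#'
#' @param cohort patient-level rows of one stratum (both splits).
#' @param features feature columns (default the canonical 37).
#' @param ntree forest size.
#' @param seed integer RNG seed.
#' @return list with `model`, `ranking`, and `scores` (data.frame
#'   `patient_id`, `score`, `truth` with `truth` TRUE for invasive).
#' @export
trainCancerClassifier <- function(cohort, features = featureNames(),
                                  ntree = 500, seed = 1) {
  cohort <- cohort[cohort$diagnosis != "insitu", , drop = FALSE]
  y <- factor(ifelse(cohort$diagnosis == "invasive", "invasive", "benign"),
              levels = c("benign", "invasive"))
  train <- cohort$split == "train"
  test <- cohort$split == "test"
  if (length(unique(y[train])) < 2L)
    stop(degenerateStratumError("training split lacks a class"))
  if (length(unique(y[test])) < 2L)
    stop(degenerateStratumError("test split lacks a class"))
  x <- cohort[, features, drop = FALSE]
  fit <- withSeed(seed,
    randomForest::randomForest(x = x[train, , drop = FALSE], y = y[train],
                               ntree = ntree))
  imp <- fit$importance[, "MeanDecreaseGini"]
  scores <- predict(fit, newdata = x[test, , drop = FALSE],
                    type = "prob")[, "invasive"]
  list(model = fit, ranking = rankImportance(imp),
       scores = data.frame(patient_id = cohort$patient_id[test],
                           score = as.numeric(scores),
                           truth = y[test] == "invasive"))
}
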