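makeRegressionTable <- function(n = 300, p = 8, seed = 1,
                                targetFrom = "f1") {
  set.seed(seed)
  x <- as.data.frame(matrix(rnorm(n * p), n, p,
                            dimnames = list(NULL, paste0("f", 1:p))))
  x$patient_id <- sprintf("p%03d", seq_len(n))
  x$split <- rep(c("train", "test"), c(round(0.7 * n), n - round(0.7 * n)))
  x$global_fgv <- if (is.null(targetFrom)) rnorm(n) else x[[targetFrom]]
  x
}

test_that("the feature equal to the target is ranked most important", {
  tab <- makeRegressionTable()
  fit <- trainFgvRegressor(tab, "global_fgv", features = paste0("f", 1:8),
                           ntree = 300, seed = 4)
  expect_equal(fit$ranking$feature[1], "f1")
  expect_true(all(diff(fit$ranking$importance) <= 0))
  expect_true(all(fit$ranking$importance >= 0))
  expect_equal(fit$ranking$rank, 1:8)
})

test_that("a constant target yields constant predictions", {
  tab <- makeRegressionTable()
  tab$global_fgv <- 42
  # randomForest warns about a degenerate response; the behavior under it
  # is what is being checked
  fit <- suppressWarnings(
    trainFgvRegressor(tab, "global_fgv", features = paste0("f", 1:8),
                      ntree = 200, seed = 2))
  pc <- suppressWarnings(predictAndCorrelate(fit, tab))
  expect_lt(var(pc$predictions$predicted), 1e-6)
})

test_that("missing target column and empty splits are rejected", {
  tab <- makeRegressionTable()
  expect_error(trainFgvRegressor(tab, "localized_fgv",
                                 features = paste0("f", 1:8)),
               "not found")
  fit <- trainFgvRegressor(tab, "global_fgv", features = paste0("f", 1:8),
                           ntree = 50, seed = 1)
  expect_error(predictAndCorrelate(fit, tab[tab$split == "train", ][1:2, ]),
               "at least 3")
})

test_that("held-out Spearman matches an independent rank computation", {
  tab <- makeRegressionTable(n = 120, seed = 9)
  tab$global_fgv <- tab$f1 + 0.3 * rnorm(120)
  fit <- trainFgvRegressor(tab, "global_fgv", features = paste0("f", 1:8),
                           ntree = 200, seed = 3)
  pc <- predictAndCorrelate(fit, tab)
  expect_equal(pc$spearman,
               bruteSpearman(pc$predictions$predicted,
                             pc$predictions$actual), tolerance = 1e-12)
  # trivial endpoints of the correlation itself
  expect_equal(cor(1:6, (1:6)^2, method = "spearman"), 1)
  expect_equal(bruteSpearman(c(3, 1, 4, 1.5, 9, 2.6),
                             -c(3, 1, 4, 1.5, 9, 2.6)), -1)
})

test_that("no test-split leakage: test rows influence nothing fitted", {
  tab <- makeRegressionTable(n = 150, seed = 5)
  trainOnly <- tab[tab$split == "train", ]
  f1 <- trainFgvRegressor(tab, "global_fgv", features = paste0("f", 1:8),
                          ntree = 100, seed = 7)
  f2 <- trainFgvRegressor(trainOnly, "global_fgv",
                          features = paste0("f", 1:8), ntree = 100, seed = 7)
  expect_identical(f1$ranking, f2$ranking)
  newx <- tab[tab$split == "test", paste0("f", 1:8)]
  expect_identical(predict(f1$model, newx), predict(f2$model, newx))
  expect_identical(stratifyByMedian(tab, "global_fgv")$cutpoint,
                   stratifyByMedian(trainOnly, "global_fgv")$cutpoint)
})

test_that("an empty covariate list reproduces the feature-only model", {
  tab <- makeRegressionTable(n = 100, seed = 6)
  a <- trainFgvRegressor(tab, "global_fgv", features = paste0("f", 1:8),
                         ntree = 100, seed = 11)
  b <- trainFgvRegressor(tab, "global_fgv", features = paste0("f", 1:8),
                         covariates = character(), ntree = 100, seed = 11)
  expect_identical(a$ranking, b$ranking)
})

test_that("correlated-feature pruning removes one member per tight pair", {
  set.seed(21)
  n <- 400
  ind <- as.data.frame(matrix(rnorm(n * 4), n, 4,
                              dimnames = list(NULL, paste0("ind", 1:4))))
  base <- rnorm(n)
  dup <- data.frame(d1 = base, d2 = base, d3 = base)
  tab <- cbind(dup, ind)
  for (s in c(1, 2, 17, 99)) {
    kept <- pruneCorrelated(tab, threshold = 0.85, seed = s)
    expect_length(kept, 5)
    expect_equal(sum(startsWith(kept, "d")), 1)
    expect_identical(kept, pruneCorrelated(tab, threshold = 0.85, seed = s))
  }
  expect_length(pruneCorrelated(ind, threshold = 0.85, seed = 1), 4)
  two <- data.frame(a = base, b = base)
  expect_length(pruneCorrelated(two, threshold = 0.85, seed = 3), 1)
  expect_error(pruneCorrelated(tab, threshold = 1.5), "threshold")
  expect_error(pruneCorrelated(tab, threshold = 0), "threshold")
})

test_that("median stratification uses the train cutpoint with ties low", {
  tab <- data.frame(patient_id = sprintf("p%02d", 1:6),
                    split = c(rep("train", 4), "test", "test"),
                    global_fgv = c(10, 20, 30, 40, 25, 26))
  st <- stratifyByMedian(tab, "global_fgv")
  expect_equal(st$cutpoint, 25)
  expect_equal(st$stratum, c("low", "low", "high", "high", "low", "high"))

  same <- tab; same$global_fgv <- 7
  expect_true(all(stratifyByMedian(same, "global_fgv")$stratum == "low"))

  # a patient at 36.2 against the published-style cutpoint 34.4 is high
  tr <- data.frame(patient_id = c("a", "b", "c"), split = "train",
                   global_fgv = c(30.0, 34.4, 38.8))
  st2 <- stratifyByMedian(rbind(tr, data.frame(patient_id = "d",
                                               split = "test",
                                               global_fgv = 36.2)),
                          "global_fgv")
  expect_equal(st2$cutpoint, 34.4)
  expect_equal(st2$stratum[4], "high")
})

makeClassTable <- function(n = 200, seed = 1, sep = 3, insitu = 0) {
  set.seed(seed)
  diagnosis <- sample(rep(c("invasive", "benign_nonproliferative",
                            "proliferative", "insitu"),
                          c(round(0.3 * n), n - round(0.3 * n) - insitu -
                            round(0.1 * n), round(0.1 * n), insitu)))
  inv <- diagnosis == "invasive"
  data.frame(patient_id = sprintf("p%03d", seq_len(n)),
             split = rep(c("train", "test"), c(round(0.7 * n),
                                               n - round(0.7 * n))),
             diagnosis = diagnosis,
             f1 = sep * inv + rnorm(n),
             f2 = rnorm(n))
}

test_that("a separating feature gives test AUC 1 and top importance rank", {
  tab <- makeClassTable(sep = 50)
  clf <- trainCancerClassifier(tab, features = c("f1", "f2"), ntree = 200,
                               seed = 5)
  expect_equal(clf$ranking$feature[1], "f1")
  expect_equal(auc(rocAuc(clf$scores$score, clf$scores$truth)), 1)
})

test_that("in-situ patients are excluded before fitting and scoring", {
  tab <- makeClassTable(n = 220, seed = 3, insitu = 20)
  clean <- tab[tab$diagnosis != "insitu", ]
  a <- trainCancerClassifier(tab, features = c("f1", "f2"), ntree = 100,
                             seed = 9)
  b <- trainCancerClassifier(clean, features = c("f1", "f2"), ntree = 100,
                             seed = 9)
  expect_identical(a$scores, b$scores)
  expect_identical(a$ranking, b$ranking)
  expect_false(any(a$scores$patient_id %in%
                   tab$patient_id[tab$diagnosis == "insitu"]))
})

test_that("single-class strata raise a degenerate-stratum error", {
  tab <- makeClassTable()
  tab$diagnosis <- "benign_nonproliferative"
  expect_error(trainCancerClassifier(tab, features = c("f1", "f2")),
               class = "degenerateStratumError")
  tab2 <- makeClassTable()
  tab2$diagnosis[tab2$split == "test"] <- "proliferative"
  expect_error(trainCancerClassifier(tab2, features = c("f1", "f2")),
               class = "degenerateStratumError")
})

test_that("patient-level diagnosis collapses to the worst across biopsies", {
  meta <- data.frame(patient_id = c("p1", "p1", "p2"),
                     slide_id = c("p1_s1", "p1_s2", "p2_s1"),
                     split = c("train", "train", "test"),
                     diagnosis = c("proliferative", "invasive", "atypia"),
                     global_fgv = c(40, 40, 50),
                     localized_fgv = c(42, 42, 55),
                     bmi = 25, menopause = "pre")
  feats <- data.frame(patient_id = c("p1", "p2"), f1 = c(0.5, 0.7),
                      no_epithelium = FALSE)
  tab <- buildCohortTable(feats, meta)
  expect_equal(tab$diagnosis[tab$patient_id == "p1"], "invasive")
  expect_equal(nrow(tab), 2)
})
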