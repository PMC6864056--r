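#' Assemble a pipeline configuration
#'
#' Bundles the options of every stage: synthetic-cohort simulation (or a
#' pre-existing metadata table + maps directory), feature extraction, model
#' fitting and ROC evaluation. All randomness downstream flows from `seed`.
#'
#' @param simulation a [SimulationConfig-class] used when no external
#'   metadata is supplied.
#' @param metadata optional path to a slide-level metadata CSV (columns as
#'   written by [generateCohort()]); its `path` column is resolved relative
#'   to `mapsDir`.
#' @param mapsDir directory containing the label maps referenced by
#'   `metadata`.
#' @param minRegionArea minimum epithelial region area kept (um^2).
#' @param ntree random-forest size for both model stages.
#' @param pruneThreshold Spearman threshold of the correlated-feature
#'   pruning sensitivity analysis (default 0.85).
#' @param covariates extra covariate columns for the density regression
#'   (e.g. `"bmi"`).
#' @param nBootstrap bootstrap replicates for CIs and AUC comparisons.
#' @param ciLevel confidence level of the bootstrap intervals.
#' @param seed master integer seed; every stage derives its own stream from
#'   it.
#' @return a list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(simulation = simulationConfig(),
                           metadata = NULL, mapsDir = NULL,
                           minRegionArea = 50, ntree = 500,
                           pruneThreshold = 0.85,
                           covariates = character(),
                           nBootstrap = 2000, ciLevel = 0.95, seed = 11) {
  structure(list(simulation = simulation, metadata = metadata,
                 mapsDir = mapsDir, minRegionArea = minRegionArea,
                 ntree = ntree, pruneThreshold = pruneThreshold,
                 covariates = covariates, nBootstrap = nBootstrap,
                 ciLevel = ciLevel, seed = seed),
            class = "pipelineConfig")
}

snakeToCamel <- function(x) {
  gsub("_(\\w)", "\\U\\1", x, perl = TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipelineConfig()] (snake_case
#' accepted); the `simulation` block mirrors [simulationConfig()].
#'
#' @param path YAML file path.
#' @return a `"pipelineConfig"` list.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()  # empty file -> all defaults
  names(raw) <- snakeToCamel(names(raw))
  sim <- simulationConfig()
  if (!is.null(raw$simulation)) {
    args <- raw$simulation
    names(args) <- snakeToCamel(names(args))
    sim <- do.call(simulationConfig, args)
  }
  raw$simulation <- NULL
  do.call(pipelineConfig, c(list(simulation = sim), raw))
}

configAsList <- function(config) {
  sim <- config$simulation
  simList <- sapply(slotNames(sim), function(s) slot(sim, s),
                    simplify = FALSE)
  out <- unclass(config)
  out$simulation <- simList
  out
}

reportAsList <- function(rr) {
  list(stratum = rr@stratum, auc = rr@auc, ci_low = rr@ciLow,
       ci_high = rr@ciHigh, level = rr@level,
       n_bootstrap = rr@nBootstrap, seed = rr@seed)
}

comparisonAsList <- function(cmp) {
  list(auc_a = cmp@aucA, auc_b = cmp@aucB, statistic = cmp@statistic,
       p_value = cmp@pValue, n_bootstrap = cmp@nBootstrap, seed = cmp@seed)
}

writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Run the full pipeline: simulate, extract, model, evaluate
#'
#' Executes, in order: cohort simulation (unless an external metadata table
#' is configured), per-slide and per-patient feature extraction,
#' random-forest density regression for the global and localized targets
#' (with importance rankings, held-out Spearman correlations and the
#' correlated-feature pruning sensitivity analysis), and stratified
#' invasive-vs-benign classification in the four strata high/low x
#' global/localized, each evaluated with a stratified percentile-bootstrap
#' ROC report plus the two high-vs-low AUC comparisons. Artifacts are
#' written to `outDir` as CSV/JSON together with a run manifest; rerunning
#' with the same configuration reproduces them numerically.
#'
#' If a stratum lacks a class (e.g. no invasive patients), the pipeline
#' stops at the classification stage with a `degenerateStratumError`; the
#' regression artifacts written before it remain on disk.
#'
#' @param config a `"pipelineConfig"` list from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @param outDir output directory, created if needed.
#' @return Invisibly, a list with `summary` (key numbers: Spearman
#'   correlations, stratum AUCs and CIs, comparison p-values, pruning
#'   retention), `cohort` (the patient-level table) and `artifacts` (paths).
#' @export
runFullPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  artifacts <- character()
  keep <- function(p) { artifacts <<- c(artifacts, p); p }

  cfgPath <- keep(file.path(outDir, "config.yaml"))
  yaml::write_yaml(configAsList(config), cfgPath)

  ## stage 1: cohort (simulated or external)
  if (is.null(config$metadata)) {
    sim <- config$simulation
    sim@rngSeed <- deriveSeed(seed, 1)
    dataDir <- file.path(outDir, "data")
    meta <- generateCohort(sim, dataDir)
    mpp <- sim@micronsPerPixel
  } else {
    meta <- read.csv(config$metadata)
    dataDir <- if (is.null(config$mapsDir)) dirname(config$metadata) else
      config$mapsDir
    mpp <- config$simulation@micronsPerPixel
  }

  ## stage 2: features
  slideFeat <- extractFeaturesCohort(meta, dataDir, micronsPerPixel = mpp,
                                     minRegionArea = config$minRegionArea)
  write.csv(slideFeat, keep(file.path(outDir, "slide_features.csv")),
            row.names = FALSE)
  patientFeat <- aggregateCohort(slideFeat)
  write.csv(patientFeat, keep(file.path(outDir, "patient_features.csv")),
            row.names = FALSE)
  cohort <- buildCohortTable(patientFeat, meta)

  ## stage 3: density regression (global + localized)
  fgv <- list()
  for (target in c("global_fgv", "localized_fgv")) {
    fit <- trainFgvRegressor(cohort, target, covariates = config$covariates,
                             ntree = config$ntree,
                             seed = deriveSeed(seed, 2 + match(target,
                               c("global_fgv", "localized_fgv"))))
    pc <- predictAndCorrelate(fit, cohort)
    write.csv(fit$ranking,
              keep(file.path(outDir, paste0("ranking_", target, ".csv"))),
              row.names = FALSE)
    write.csv(pc$predictions,
              keep(file.path(outDir, paste0("predictions_", target, ".csv"))),
              row.names = FALSE)
    fgv[[target]] <- list(spearman = pc$spearman,
                          top_features = fit$ranking$feature[1:5])
  }
  trainRows <- cohort$split == "train"
  retained <- pruneCorrelated(cohort[trainRows, featureNames()],
                              threshold = config$pruneThreshold,
                              seed = deriveSeed(seed, 5))
  fgvReport <- list(global_fgv = fgv$global_fgv,
                    localized_fgv = fgv$localized_fgv,
                    pruning = list(threshold = config$pruneThreshold,
                                   n_retained = length(retained),
                                   retained = retained))
  writeJson(fgvReport, keep(file.path(outDir, "fgv_report.json")))

  ## stage 4: stratified classification + evaluation
  evalReports <- list()
  for (target in c("global_fgv", "localized_fgv")) {
    st <- stratifyByMedian(cohort, target)
    scores <- list()
    rocs <- list()
    for (lev in c("high", "low")) {
      sub <- cohort[st$stratum == lev, , drop = FALSE]
      clf <- trainCancerClassifier(sub, ntree = config$ntree,
                                   seed = deriveSeed(seed,
                                     10 + match(target, c("global_fgv",
                                       "localized_fgv")) * 2 +
                                     (lev == "low")))
      tag <- paste0(lev, "_", target)
      write.csv(clf$scores,
                keep(file.path(outDir, paste0("scores_", tag, ".csv"))),
                row.names = FALSE)
      write.csv(clf$ranking,
                keep(file.path(outDir, paste0("ranking_cancer_", tag,
                                              ".csv"))),
                row.names = FALSE)
      rocs[[lev]] <- bootstrapAucCi(clf$scores$score, clf$scores$truth,
                                    nBootstrap = config$nBootstrap,
                                    level = config$ciLevel,
                                    seed = deriveSeed(seed, 20 +
                                      match(target, c("global_fgv",
                                        "localized_fgv")) * 2 +
                                      (lev == "low")),
                                    stratum = tag)
      scores[[lev]] <- clf$scores
    }
    cmp <- compareAucBootstrap(scores$high$score, scores$high$truth,
                               scores$low$score, scores$low$truth,
                               nBootstrap = config$nBootstrap,
                               seed = deriveSeed(seed, 30 +
                                 match(target, c("global_fgv",
                                   "localized_fgv"))))
    evalReports[[target]] <- list(cutpoint = st$cutpoint,
                                  high = rocs$high, low = rocs$low,
                                  comparison = cmp)
    writeJson(list(cutpoint = st$cutpoint,
                   high = reportAsList(rocs$high),
                   low = reportAsList(rocs$low),
                   comparison = comparisonAsList(cmp)),
              keep(file.path(outDir, paste0("evaluation_", target,
                                            ".json"))))
  }

  ## manifest
  stratumCounts <- sapply(c("global_fgv", "localized_fgv"),
    function(target) {
      st <- stratifyByMedian(cohort, target)
      tab <- table(stratum = st$stratum, split = cohort$split)
      apply(tab, 1, as.list, simplify = FALSE)
    }, simplify = FALSE)
  manifest <- list(
    package = "HistoDensity",
    version = as.character(packageVersion("HistoDensity")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfgPath)),
    n_patients = nrow(cohort),
    n_slides = nrow(slideFeat),
    n_train = sum(cohort$split == "train"),
    n_test = sum(cohort$split == "test"),
    n_roc_reports = 4, n_auc_comparisons = 2,
    stratum_counts = stratumCounts,
    artifacts = basename(artifacts))
  writeJson(manifest, keep(file.path(outDir, "manifest.json")))

  summary <- list(
    spearman_global = fgv$global_fgv$spearman,
    spearman_localized = fgv$localized_fgv$spearman,
    evaluation = evalReports,
    pruning_retained = length(retained))
  invisible(list(summary = summary, cohort = cohort, artifacts = artifacts,
                 manifest = manifest))
}
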