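#' Tissue-class label map for one slide
#'
#' A `TissueMap` holds the per-pixel tissue classification of a whole-slide
#' image as an integer matrix with codes 0 (background glass), 1 (epithelium),
#' 2 (non-fatty stroma) and 3 (fat), together with the physical pixel size.
#' All per-slide feature extraction starts from this object.
#'
#' @slot labels integer matrix of tissue codes (rows x cols, 0-based pixel
#'   coordinates are row-major in the feature code).
#' @slot micronsPerPixel positive scalar, physical edge length of one pixel
#'   in micrometres.
#' @slot slideId character identifier.
#'
#' @export
setClass("TissueMap",
  representation(labels = "matrix", micronsPerPixel = "numeric",
                 slideId = "character"),
  validity = function(object) {
    msg <- character()
    lb <- object@labels
    if (!is.numeric(lb) && !is.integer(lb))
      msg <- c(msg, "labels must be an integer matrix")
    if (length(lb) == 0L) msg <- c(msg, "labels must be non-empty")
    else if (!all(lb %in% 0:3))
      msg <- c(msg, "labels may contain only codes {0,1,2,3}")
    if (length(object@micronsPerPixel) != 1L ||
        !is.finite(object@micronsPerPixel) || object@micronsPerPixel <= 0)
      msg <- c(msg, "micronsPerPixel must be a positive scalar")
    if (length(object@slideId) != 1L)
      msg <- c(msg, "slideId must be a single string")
    if (length(msg)) msg else TRUE
  })

#' Construct a TissueMap
#'
#' @param labels integer matrix with codes 0 (background), 1 (epithelium),
#'   2 (stroma), 3 (fat).
#' @param micronsPerPixel physical pixel size in micrometres (default 0.5,
#'   i.e. a x20 scan).
#' @param slideId slide identifier.
#' @return A [TissueMap-class] object.
#' @examples
#' m <- matrix(0L, 8, 8); m[3:6, 3:6] <- 1L
#' TissueMap(m, micronsPerPixel = 0.5, slideId = "demo")
#' @export
TissueMap <- function(labels, micronsPerPixel = 0.5, slideId = "slide") {
  storage.mode(labels) <- "integer"
  new("TissueMap", labels = labels,
      micronsPerPixel = as.numeric(micronsPerPixel),
      slideId = as.character(slideId))
}

#' Configuration of the synthetic label-map cohort generator
#'
#' Defines the simulated study conditions: image geometry, cohort size, mean
#' tissue composition, epithelial region geometry and spatial organization,
#' noise levels and diagnosis mix. Fractions `fatFraction`, `stromaFraction`
#' and `epiFraction` are proportions of the tissue area and must sum to 1;
#' `backgroundFraction` is the proportion of the image that is glass.
#'
#' @seealso [simulationConfig()] for defaults and field documentation.
#' @export
setClass("SimulationConfig",
  representation(
    imageHeight = "numeric", imageWidth = "numeric",
    micronsPerPixel = "numeric",
    nPatients = "numeric", slidesPerPatient = "numeric",
    fatFraction = "numeric", stromaFraction = "numeric",
    epiFraction = "numeric", backgroundFraction = "numeric",
    epiRegionCountMean = "numeric", epiRegionAreaMean = "numeric",
    epiEccentricityMean = "numeric",
    clusteringMode = "character",
    fgvNoiseSd = "numeric", invasiveFraction = "numeric",
    insituFraction = "numeric",
    compositionSd = "numeric", epiFractionSd = "numeric",
    slideJitterSd = "numeric", localizedSd = "numeric",
    rngSeed = "numeric"),
  validity = function(object) {
    msg <- character()
    fr <- c(object@fatFraction, object@stromaFraction, object@epiFraction)
    if (abs(sum(fr) - 1) > 1e-9)
      msg <- c(msg, "fat/stroma/epi fractions must sum to 1")
    if (any(fr < 0 | fr > 1) || object@backgroundFraction < 0 ||
        object@backgroundFraction > 1)
      msg <- c(msg, "all fractions must lie in [0, 1]")
    if (object@imageHeight < 8 || object@imageWidth < 8)
      msg <- c(msg, "image dimensions must be at least 8 pixels")
    if (object@nPatients < 1 || object@slidesPerPatient < 1)
      msg <- c(msg, "patient and slide counts must be positive")
    if (object@micronsPerPixel <= 0)
      msg <- c(msg, "micronsPerPixel must be positive")
    if (object@epiEccentricityMean < 0 || object@epiEccentricityMean >= 1)
      msg <- c(msg, "epiEccentricityMean must lie in [0, 1)")
    if (!object@clusteringMode %in% c("dispersed", "clustered", "coalescent"))
      msg <- c(msg, "clusteringMode must be dispersed, clustered or coalescent")
    if (object@invasiveFraction < 0 || object@invasiveFraction > 1 ||
        object@insituFraction < 0 || object@insituFraction > 1)
      msg <- c(msg, "diagnosis fractions must lie in [0, 1]")
    if (object@fgvNoiseSd < 0) msg <- c(msg, "fgvNoiseSd must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' ROC report with optional bootstrap confidence interval
#'
#' @slot auc area under the ROC curve (Mann-Whitney concordance, ties 1/2).
#' @slot ciLow,ciHigh percentile-bootstrap confidence limits (`NA` when no
#'   bootstrap was run).
#' @slot level confidence level of the interval.
#' @slot nBootstrap number of bootstrap replicates (0 when none).
#' @slot rocPoints data.frame with columns `fpr`, `tpr`, `threshold`.
#' @slot replicates numeric vector of bootstrap AUC replicates.
#' @slot stratum label of the patient stratum the report refers to.
#' @slot seed RNG seed used for the bootstrap.
#' @export
setClass("RocReport",
  representation(auc = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 level = "numeric", nBootstrap = "numeric",
                 rocPoints = "data.frame", replicates = "numeric",
                 stratum = "character", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.na(object@auc) && (object@auc < 0 || object@auc > 1))
      msg <- c(msg, "auc must lie in [0, 1]")
    if (!is.na(object@ciLow) && !is.na(object@ciHigh)) {
      if (object@ciLow > object@auc + 1e-12 ||
          object@ciHigh < object@auc - 1e-12)
        msg <- c(msg, "confidence interval must contain the AUC estimate")
    }
    rp <- object@rocPoints
    if (nrow(rp) > 0) {
      if (any(diff(rp$fpr) < -1e-12) || any(diff(rp$tpr) < -1e-12))
        msg <- c(msg, "ROC points must be monotone non-decreasing")
    }
    if (length(msg)) msg else TRUE
  })

#' Bootstrap comparison of two AUCs from independent patient sets
#'
#' @slot aucA,aucB observed AUCs of the two classifiers.
#' @slot statistic standardized AUC difference
#'   (aucA - aucB) / sd(bootstrap differences).
#' @slot pValue two-sided p-value from the standard normal law.
#' @slot nBootstrap number of bootstrap replicates.
#' @slot seed RNG seed used.
#' @export
setClass("AucComparison",
  representation(aucA = "numeric", aucB = "numeric", statistic = "numeric",
                 pValue = "numeric", nBootstrap = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.na(object@pValue) &&
        (object@pValue < 0 || object@pValue > 1))
      msg <- c(msg, "pValue must lie in [0, 1]")
    d <- object@aucA - object@aucB
    if (!is.na(object@statistic) && object@statistic != 0 &&
        sign(object@statistic) != sign(d))
      msg <- c(msg, "statistic sign must match sign of AUC difference")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "TissueMap", function(object) {
  lb <- object@labels
  cat(sprintf("TissueMap '%s': %d x %d px @ %.3g um/px\n",
              object@slideId, nrow(lb), ncol(lb), object@micronsPerPixel))
  tab <- tabulate(lb + 1L, nbins = 4L)
  cat(sprintf("  background %d | epithelium %d | stroma %d | fat %d px\n",
              tab[1], tab[2], tab[3], tab[4]))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d patients x %d slide(s), %dx%d px @ %.3g um/px\n",
    object@nPatients, object@slidesPerPatient, object@imageHeight,
    object@imageWidth, object@micronsPerPixel))
  cat(sprintf("  mean composition fat/stroma/epi = %.2f/%.2f/%.2f, seed %d\n",
              object@fatFraction, object@stromaFraction, object@epiFraction,
              as.integer(object@rngSeed)))
})

setMethod("show", "RocReport", function(object) {
  cat(sprintf("RocReport%s: AUC = %.3f",
              if (nzchar(object@stratum))
                paste0(" [", object@stratum, "]") else "", object@auc))
  if (!is.na(object@ciLow))
    cat(sprintf(" (%d%% CI: %.3f-%.3f, B = %d)",
                round(100 * object@level), object@ciLow, object@ciHigh,
                as.integer(object@nBootstrap)))
  cat("\n")
})

setMethod("show", "AucComparison", function(object) {
  cat(sprintf(
    "AucComparison: AUC %.3f vs %.3f, D = %.3f, p = %.3g (B = %d)\n",
    object@aucA, object@aucB, object@statistic, object@pValue,
    as.integer(object@nBootstrap)))
})

#' @describeIn TissueMap-class label matrix accessor
#' @param x a `TissueMap`
#' @export
tissueLabels <- function(x) {
  stopifnot(is(x, "TissueMap"))
  x@labels
}

#' @describeIn TissueMap-class pixel size accessor (micrometres)
#' @export
micronsPerPixel <- function(x) {
  stopifnot(is(x, "TissueMap"))
  x@micronsPerPixel
}

#' @describeIn TissueMap-class slide identifier accessor
#' @export
slideId <- function(x) {
  stopifnot(is(x, "TissueMap"))
  x@slideId
}

#' AUC accessor
#' @param x a [RocReport-class]
#' @return the AUC estimate.
#' @export
auc <- function(x) {
  stopifnot(is(x, "RocReport"))
  x@auc
}

#' Confidence-interval accessor
#' @param x a [RocReport-class]
#' @return numeric length-2 vector (lower, upper).
#' @export
ciLimits <- function(x) {
  stopifnot(is(x, "RocReport"))
  c(x@ciLow, x@ciHigh)
}

#' P-value accessor
#' @param x an [AucComparison-class]
#' @export
pValue <- function(x) {
  stopifnot(is(x, "AucComparison"))
  x@pValue
}
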