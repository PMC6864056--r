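summaryStatNames <- c("mean", "median", "sd", "iq", "max")

#' Canonical 37-feature roster
#'
#' Names of the per-slide features, grouped into four families: global tissue
#' quantities (6), epithelial-region morphology (11: region count plus
#' area and eccentricity summarized by mean, median, SD, interquartile range
#' and maximum), area-Voronoi spatial arrangement (15: influence-zone area,
#' epithelium-to-Voronoi ratio and epithelium-to-non-epithelium ratio, each
#' summarized the same way) and Delaunay spatial arrangement (5: neighbor
#' counts summarized the same way).
#'
#' @return character vector of length 37.
#' @export
featureNames <- function() {
  c("fat_amount", "fat_amount_norm", "stroma_amount", "stroma_amount_norm",
    "epi_amount", "epi_amount_norm",
    "n_epi_regions",
    paste0("epi_area_", summaryStatNames),
    paste0("epi_ecc_", summaryStatNames),
    paste0("voronoi_area_", summaryStatNames),
    paste0("ratio_epi_voronoi_", summaryStatNames),
    paste0("ratio_epi_nonepi_", summaryStatNames),
    paste0("delaunay_neighbors_", summaryStatNames))
}

#' Feature-family lookup
#'
#' @return named character vector mapping each of the 37 feature names to its
#'   family: `"global"`, `"morphology"`, `"voronoi"` or `"delaunay"`.
#' @export
featureFamilies <- function() {
  fn <- featureNames()
  fam <- c(rep("global", 6), rep("morphology", 11), rep("voronoi", 15),
           rep("delaunay", 5))
  names(fam) <- fn
  fam
}

#' Extract epithelial regions from a tissue map
#'
#' Connected components of the epithelium label under 8-connectivity, with
#' physical area, centroid and eccentricity of the moment-equivalent ellipse
#' (eigen-decomposition of the central second moments of the pixel
#' coordinates; 0 = circular, approaching 1 = line-like). Components smaller
#' than `minRegionArea` are discarded and the survivors relabeled 1..k in
#' scan order; that label is the canonical `region_label` used for Voronoi
#' tie-breaking.
#'
#' @param map a [TissueMap-class].
#' @param minRegionArea minimum region area kept, in square micrometres
#'   (default 50, suppressing single-pixel segmentation noise).
#' @return data.frame with columns `region_label`, `n_pixels`, `area` (um^2),
#'   `centroid_row`, `centroid_col` (0-based pixel coordinates) and
#'   `eccentricity`; the filtered component image (integer matrix) is
#'   attached as attribute `"componentImage"`. Zero rows when the slide has
#'   no (sufficiently large) epithelium.
#' @export
extractRegions <- function(map, minRegionArea = 50) {
  stopifnot(is(map, "TissueMap"))
  validObject(map)
  mpp2 <- map@micronsPerPixel^2
  lab <- cpp_label_components(map@labels == 1L)
  K <- attr(lab, "n_components")
  empty <- data.frame(region_label = integer(), n_pixels = integer(),
                      area = numeric(), centroid_row = numeric(),
                      centroid_col = numeric(), eccentricity = numeric())
  if (K == 0L) {
    attr(empty, "componentImage") <- matrix(0L, nrow(map@labels),
                                            ncol(map@labels))
    return(empty)
  }
  mom <- cpp_region_moments(lab, K)
  keep <- which(mom[, 1] * mpp2 >= minRegionArea)
  if (length(keep) == 0L) {
    attr(empty, "componentImage") <- matrix(0L, nrow(map@labels),
                                            ncol(map@labels))
    return(empty)
  }
  relab <- integer(K)
  relab[keep] <- seq_along(keep)
  comp <- matrix(c(0L, relab)[lab + 1L], nrow(lab), ncol(lab))
  storage.mode(comp) <- "integer"
  n <- mom[keep, 1]
  mu20 <- mom[keep, 4] / n
  mu02 <- mom[keep, 5] / n
  mu11 <- mom[keep, 6] / n
  tr <- mu20 + mu02
  det <- sqrt(pmax((mu20 - mu02)^2 + 4 * mu11^2, 0))
  l1 <- (tr + det) / 2
  l2 <- (tr - det) / 2
  ecc <- ifelse(l1 > 0, sqrt(pmax(1 - l2 / l1, 0)), 0)
  out <- data.frame(region_label = seq_along(keep),
                    n_pixels = as.integer(n), area = n * mpp2,
                    centroid_row = mom[keep, 2], centroid_col = mom[keep, 3],
                    eccentricity = ecc)
  attr(out, "componentImage") <- comp
  out
}

noEpitheliumError <- function() {
  errorCondition("no epithelial regions: Voronoi features undefined",
                 class = c("noEpitheliumError", "error", "condition"))
}

#' Area-Voronoi influence zones of epithelial regions
#'
#' Partitions the tissue mask (labels 1-3) into influence zones: every tissue
#' pixel is assigned to the region whose pixel set is nearest in Euclidean
#' distance (distance between pixel centers; a region's own pixels are at
#' distance zero). Ties are broken toward the lowest `region_label`;
#' background pixels stay unassigned (0). Distances are computed with an
#' exact per-region squared Euclidean distance transform, so the assignment
#' matches an exhaustive per-pixel scan.
#'
#' @param map a [TissueMap-class].
#' @param regions result of [extractRegions()] (its `"componentImage"`
#'   attribute carries the region pixel sets).
#' @return integer matrix of the same size as the map: influence-zone label
#'   per tissue pixel, 0 elsewhere.
#' @export
areaVoronoi <- function(map, regions) {
  stopifnot(is(map, "TissueMap"))
  if (nrow(regions) == 0L) stop(noEpitheliumError())
  comp <- attr(regions, "componentImage")
  stopifnot(!is.null(comp))
  cpp_area_voronoi(comp, map@labels >= 1L & map@labels <= 3L,
                   max(regions$region_label))
}

#' Fill the Voronoi-based ratio features of each region
#'
#' `ratio_epi_voronoi` = region area / influence-zone area (in (0, 1]; near
#' 1 means the region fills its zone, the coalescent phenotype).
#' `ratio_epi_nonepi` = region area / (zone area - region area); undefined
#' (NA) when the zone equals the region, and such values are excluded from
#' downstream summaries.
#'
#' @param regions data.frame from [extractRegions()] with a `voronoi_area`
#'   column (um^2) already filled (see [areaVoronoi()]).
#' @return `regions` with columns `ratio_epi_voronoi` and
#'   `ratio_epi_nonepi` added.
#' @export
voronoiRatios <- function(regions) {
  stopifnot("voronoi_area" %in% names(regions))
  regions$ratio_epi_voronoi <- regions$area / regions$voronoi_area
  nonepi <- regions$voronoi_area - regions$area
  regions$ratio_epi_nonepi <- ifelse(nonepi > 0, regions$area / nonepi,
                                     NA_real_)
  regions
}

#' Delaunay neighbor counts of region centroids
#'
#' Builds the Delaunay triangulation of the region centroids and records each
#' region's degree (number of incident triangulation edges). Degenerate
#' inputs fall back gracefully: a single region has degree 0, two regions
#' degree 1 each, and fully collinear centroids are chained along the line
#' (endpoints degree 1, interior points degree 2), so small biopsies still
#' yield features.
#'
#' @param regions data.frame from [extractRegions()].
#' @return `regions` with a `delaunay_degree` column added.
#' @export
delaunayDegrees <- function(regions) {
  n <- nrow(regions)
  x <- regions$centroid_col
  y <- regions$centroid_row
  if (n >= 3L && allCollinear(x, y)) {
    t <- if (stats::var(x) >= stats::var(y)) x else y
    ord <- order(t)
    deg <- integer(n)
    deg[ord] <- c(1L, rep(2L, n - 2L), 1L)
    regions$delaunay_degree <- deg
  } else {
    regions$delaunay_degree <- as.integer(cpp_delaunay_degrees(x, y))
  }
  regions
}

allCollinear <- function(x, y, tol = 1e-9) {
  n <- length(x)
  if (n < 3L) return(TRUE)
  dx <- x - x[1]; dy <- y - y[1]
  j <- which.max(dx^2 + dy^2)  # farthest point fixes the direction
  if (dx[j]^2 + dy[j]^2 == 0) return(TRUE)
  scale <- max(abs(dx), abs(dy), 1)
  all(abs(dx[j] * dy - dy[j] * dx) <= tol * scale^2)
}

# mean/median/sd/iq/max summary with the conventions used throughout:
# sample SD (0 for a single value), IQ = Q3 - Q1 with linear interpolation
summariseStat <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L)
    return(stats::setNames(rep(0, 5), summaryStatNames))
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  stats::setNames(
    c(mean(x), median(x), if (length(x) > 1L) sd(x) else 0, q[2] - q[1],
      max(x)),
    summaryStatNames)
}

emptySlideError <- function() {
  errorCondition("slide contains no tissue pixels",
                 class = c("emptySlideError", "error", "condition"))
}

#' Extract the 37-feature vector from one tissue map
#'
#' Computes global tissue quantities (class areas in um^2 and normalized to
#' percent of total tissue area), epithelial-region morphology, area-Voronoi
#' and Delaunay spatial-arrangement features, with the region-based families
#' summarized by mean, median, SD, interquartile range and maximum. Slides
#' with no (retained) epithelial region get zeros for all region-based
#' features and `no_epithelium = TRUE`, so downstream model matrices have no
#' missing cells.
#'
#' @param map a [TissueMap-class].
#' @param minRegionArea minimum epithelial region area kept (um^2).
#' @return one-row data.frame: `slide_id`, the 37 features of
#'   [featureNames()], and the logical flag `no_epithelium`.
#' @export
extractFeatures <- function(map, minRegionArea = 50) {
  stopifnot(is(map, "TissueMap"))
  mpp2 <- map@micronsPerPixel^2
  lb <- map@labels
  counts <- tabulate(lb + 1L, nbins = 4L)  # background, epi, stroma, fat
  tissuePx <- sum(counts[2:4])
  if (tissuePx == 0L) stop(emptySlideError())
  tissueArea <- tissuePx * mpp2
  out <- stats::setNames(numeric(37), featureNames())
  out["epi_amount"] <- counts[2] * mpp2
  out["stroma_amount"] <- counts[3] * mpp2
  out["fat_amount"] <- counts[4] * mpp2
  out["epi_amount_norm"] <- 100 * counts[2] / tissuePx
  out["stroma_amount_norm"] <- 100 * counts[3] / tissuePx
  out["fat_amount_norm"] <- 100 * counts[4] / tissuePx
  regions <- extractRegions(map, minRegionArea)
  noEpi <- nrow(regions) == 0L
  if (!noEpi) {
    vor <- areaVoronoi(map, regions)
    va <- tabulate(vor[vor > 0L], nbins = max(regions$region_label))
    regions$voronoi_area <- va * mpp2
    regions <- voronoiRatios(regions)
    regions <- delaunayDegrees(regions)
    out["n_epi_regions"] <- nrow(regions)
    out[paste0("epi_area_", summaryStatNames)] <- summariseStat(regions$area)
    out[paste0("epi_ecc_", summaryStatNames)] <-
      summariseStat(regions$eccentricity)
    out[paste0("voronoi_area_", summaryStatNames)] <-
      summariseStat(regions$voronoi_area)
    out[paste0("ratio_epi_voronoi_", summaryStatNames)] <-
      summariseStat(regions$ratio_epi_voronoi)
    out[paste0("ratio_epi_nonepi_", summaryStatNames)] <-
      summariseStat(regions$ratio_epi_nonepi)
    out[paste0("delaunay_neighbors_", summaryStatNames)] <-
      summariseStat(regions$delaunay_degree)
  }
  cbind(data.frame(slide_id = map@slideId), as.data.frame(as.list(out)),
        data.frame(no_epithelium = noEpi))
}

#' Extract features for every slide of a cohort
#'
#' @param metadata slide-level metadata data.frame with at least
#'   `patient_id`, `slide_id`, `path` (as written by [generateCohort()]).
#' @param dir directory the `path` column is relative to.
#' @param micronsPerPixel pixel size shared by the maps.
#' @param minRegionArea minimum epithelial region area kept (um^2).
#' @return data.frame with `patient_id`, `slide_id`, the 37 features and
#'   `no_epithelium`, one row per slide.
#' @export
extractFeaturesCohort <- function(metadata, dir, micronsPerPixel = 0.5,
                                  minRegionArea = 50) {
  paths <- file.path(dir, metadata$path)
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing label maps for slide_ids: ",
         paste(metadata$slide_id[missing], collapse = ", "))
  rows <- lapply(seq_len(nrow(metadata)), function(i) {
    map <- readTissueMap(paths[i], micronsPerPixel = micronsPerPixel,
                         slideId = metadata$slide_id[i])
    cbind(data.frame(patient_id = metadata$patient_id[i]),
          extractFeatures(map, minRegionArea))
  })
  do.call(rbind, rows)
}

#' Aggregate slide-level feature vectors to one per patient
#'
#' Per-feature median across the patient's slides; a single slide passes
#' through unchanged. The `no_epithelium` flag aggregates as "all slides
#' lacked epithelium".
#'
#' @param vectors data.frame of slide-level rows for one patient (as from
#'   [extractFeatures()]); at least one row.
#' @return one-row data.frame with the 37 features and `no_epithelium`.
#' @export
aggregatePatient <- function(vectors) {
  if (nrow(vectors) == 0L) stop("at least one slide vector is required")
  fn <- featureNames()
  out <- as.data.frame(lapply(vectors[fn], median))
  out$no_epithelium <- all(vectors$no_epithelium)
  out
}

#' Aggregate a cohort's slide-level feature table to patient level
#'
#' @param slideFeatures data.frame from [extractFeaturesCohort()].
#' @return data.frame with one row per `patient_id`.
#' @export
aggregateCohort <- function(slideFeatures) {
  pieces <- split(slideFeatures, slideFeatures$patient_id)
  out <- do.call(rbind, lapply(pieces, aggregatePatient))
  cbind(data.frame(patient_id = names(pieces)), out, row.names = NULL)
}
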