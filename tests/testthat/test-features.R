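blankMap <- function(H = 16, W = 16, fill = 2L, mpp = 0.5) {
  TissueMap(matrix(fill, H, W), micronsPerPixel = mpp, slideId = "t")
}

test_that("region extraction: empty, square, and moment eccentricity", {
  expect_equal(nrow(extractRegions(blankMap())), 0)

  m <- matrix(2L, 16, 16); m[5:8, 5:8] <- 1L
  r <- extractRegions(TissueMap(m, 0.5, "sq"), minRegionArea = 0)
  expect_equal(nrow(r), 1)
  expect_equal(r$area, 16 * 0.25)  # 16 px at 0.25 um^2/px
  expect_equal(r$centroid_row, 5.5)  # 0-based rows 4..7
  expect_equal(r$eccentricity, 0)

  m2 <- matrix(2L, 16, 16); m2[3:12, 4:5] <- 1L  # 10 x 2 rectangle
  r2 <- extractRegions(TissueMap(m2, 0.5, "rect"), minRegionArea = 0)
  rows <- rep(2:11, times = 2); cols <- rep(3:4, each = 10)
  expect_equal(r2$eccentricity, bruteEccentricity(rows, cols),
               tolerance = 1e-12)
  expect_equal(r2$eccentricity, sqrt(1 - 0.25 / 8.25), tolerance = 1e-12)
})

test_that("min-area filter and 8-connectivity behave as specified", {
  m <- matrix(2L, 20, 20)
  m[2:5, 2:5] <- 1L          # 16 px = 4 um^2
  m[10, 10] <- 1L            # 1 px = 0.25 um^2
  m[11, 11] <- 1L            # diagonal neighbor: same component under 8-conn
  tm <- TissueMap(m, 0.5, "f")
  expect_equal(nrow(extractRegions(tm, minRegionArea = 0)), 2)
  expect_equal(nrow(extractRegions(tm, minRegionArea = 1)), 1)
})

test_that("global amounts and normalization are exact", {
  m <- matrix(0L, 40, 40)
  m[1:25, 1:40] <- 3L                 # 1000 tissue px total
  m[1:25, 1:10] <- 2L                 # 250 of them stroma
  f <- extractFeatures(TissueMap(m, 0.5, "g"))
  expect_equal(f$stroma_amount_norm, 25)
  expect_equal(f$fat_amount_norm, 75)
  expect_equal(f$epi_amount_norm, 0)
  expect_equal(f$stroma_amount, 250 * 0.25)
  expect_true(f$no_epithelium)
  expect_equal(f$n_epi_regions, 0)

  allFat <- extractFeatures(blankMap(fill = 3L))
  expect_equal(allFat$fat_amount_norm, 100)
  expect_equal(allFat$stroma_amount_norm, 0)

  expect_error(extractFeatures(blankMap(fill = 0L)), class = "emptySlideError")
})

test_that("normalized amounts always sum to 100 on generated maps", {
  cfg <- simulationConfig(imageHeight = 96, imageWidth = 96)
  for (s in 1:5) {
    f <- extractFeatures(generateTissueMap(cfg, seed = s), minRegionArea = 5)
    expect_equal(f$fat_amount_norm + f$stroma_amount_norm + f$epi_amount_norm,
                 100, tolerance = 1e-6)
    expect_true(all(unlist(f[paste0(c("fat", "stroma", "epi"),
                                    "_amount_norm")]) >= 0))
  }
})

test_that("relabeling stroma to fat leaves epithelial features unchanged", {
  cfg <- simulationConfig(imageHeight = 96, imageWidth = 96)
  m <- generateTissueMap(cfg, seed = 11)
  f1 <- extractFeatures(m, minRegionArea = 5)
  lb <- tissueLabels(m)
  lb[lb == 2L] <- 3L
  f2 <- extractFeatures(TissueMap(lb, micronsPerPixel(m), "relab"),
                        minRegionArea = 5)
  epiCols <- setdiff(featureNames(),
                     c("fat_amount", "fat_amount_norm",
                       "stroma_amount", "stroma_amount_norm"))
  expect_equal(f2[, epiCols], f1[, epiCols], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(f2$stroma_amount_norm, f1$stroma_amount_norm)
  expect_equal(f2$stroma_amount_norm, 0)
})

test_that("doubling the pixel size scales areas by 4, dimensionless intact", {
  cfg <- simulationConfig(imageHeight = 96, imageWidth = 96)
  m <- generateTissueMap(cfg, seed = 13)
  f1 <- extractFeatures(m, minRegionArea = 5)
  m2 <- TissueMap(tissueLabels(m), micronsPerPixel = 1, slideId = "x2")
  f2 <- extractFeatures(m2, minRegionArea = 5 * 4)  # same pixel threshold
  areaCols <- c("fat_amount", "stroma_amount", "epi_amount",
                paste0("epi_area_", c("mean", "median", "sd", "iq", "max")),
                paste0("voronoi_area_", c("mean", "median", "sd", "iq",
                                          "max")))
  dimlessCols <- setdiff(featureNames(), areaCols)
  expect_equal(unlist(f2[areaCols]), 4 * unlist(f1[areaCols]),
               tolerance = 1e-12)
  expect_equal(unlist(f2[dimlessCols]), unlist(f1[dimlessCols]),
               tolerance = 1e-12)
})

test_that("summary statistics match an independent sort-based computation", {
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(sample(1:20, 1))
    got <- HistoDensity:::summariseStat(x)
    expect_equal(unname(got), unname(bruteSummary(x)), tolerance = 1e-12)
  }
  expect_equal(unname(HistoDensity:::summariseStat(c(2, NA, 4))[c(1, 3)]),
               c(3, sqrt(2)))
})

test_that("patient aggregation is the per-feature median across slides", {
  cfg <- simulationConfig(imageHeight = 96, imageWidth = 96)
  rows <- do.call(rbind, lapply(1:3, function(s)
    extractFeatures(generateTissueMap(cfg, seed = 40 + s),
                    minRegionArea = 5)))
  agg <- aggregatePatient(rows)
  for (fn in featureNames())
    expect_equal(agg[[fn]], sort(rows[[fn]])[2])  # median of 3 = 2nd order stat

  one <- aggregatePatient(rows[1, ])
  expect_equal(one[featureNames()], rows[1, featureNames()],
               ignore_attr = TRUE)

  two <- rows[1:2, ]; two$stroma_amount_norm <- c(20, 40)
  expect_equal(aggregatePatient(two)$stroma_amount_norm, 30)
  expect_error(aggregatePatient(rows[0, ]), "at least one")
})

test_that("the feature roster has 37 named members in 4 families", {
  fn <- featureNames()
  expect_length(fn, 37)
  expect_false(anyDuplicated(fn) > 0)
  fam <- featureFamilies()
  expect_identical(names(fam), fn)
  expect_equal(unname(table(fam)[c("global", "morphology", "voronoi",
                                   "delaunay")]),
               c(6L, 11L, 15L, 5L), ignore_attr = TRUE)
})
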