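test_that("degenerate compositions produce the expected maps", {
  cfg <- simulationConfig(imageHeight = 64, imageWidth = 64,
                          fatFraction = 0, stromaFraction = 1,
                          epiFraction = 0)
  m <- generateTissueMap(cfg, seed = 1)
  lb <- tissueLabels(m)
  expect_equal(sum(lb == 1), 0)
  expect_equal(sum(lb == 3), 0)
  expect_equal(sum(lb == 2), sum(lb > 0))

  cfg2 <- simulationConfig(imageHeight = 64, imageWidth = 64,
                           backgroundFraction = 0)
  m2 <- generateTissueMap(cfg2, seed = 2)
  expect_true(all(tissueLabels(m2) %in% 1:3))
})

test_that("realized composition tracks the requested one", {
  cfg <- simulationConfig(imageHeight = 256, imageWidth = 256,
                          epiRegionCountMean = 10)
  m <- generateTissueMap(cfg, seed = 7)
  lb <- tissueLabels(m)
  tissue <- sum(lb > 0)
  expect_gte(sum(lb == 1) / tissue, 0.07)
  expect_lte(sum(lb == 1) / tissue, 0.13)
  expect_lt(abs(sum(lb == 2) / tissue - cfg@stromaFraction), 0.03)
  expect_lt(abs(sum(lb == 3) / tissue - cfg@fatFraction), 0.03)
})

test_that("infeasible composition is refused", {
  cfg <- simulationConfig(imageHeight = 64, imageWidth = 64)
  state <- list(composition = c(fat = -0.5, stroma = 0.2, epi = 1.3),
                mode = "dispersed", countMean = 5, eccMean = 0.5)
  expect_error(generateTissueMap(cfg, state),
               class = "infeasibleCompositionError")
})

test_that("mean realized region count stays near the configured mean", {
  cfg <- simulationConfig()
  counts <- vapply(1:50, function(s) {
    nrow(extractRegions(generateTissueMap(cfg, seed = s), minRegionArea = 0))
  }, numeric(1))
  expect_lt(abs(mean(counts) - cfg@epiRegionCountMean),
            0.15 * cfg@epiRegionCountMean)
})

smallCohortConfig <- function(n, ...) {
  simulationConfig(imageHeight = 64, imageWidth = 64, nPatients = n,
                   slidesPerPatient = 1, epiRegionCountMean = 5, ...)
}

test_that("cohort generation is deterministic given the seed", {
  cfg <- smallCohortConfig(12, rngSeed = 99)
  d1 <- file.path(tempdir(), "coh-a"); d2 <- file.path(tempdir(), "coh-b")
  m1 <- generateCohort(cfg, d1)
  m2 <- generateCohort(cfg, d2)
  expect_identical(m1, m2)
  expect_identical(unname(tools::md5sum(file.path(d1, "cohort.csv"))),
                   unname(tools::md5sum(file.path(d2, "cohort.csv"))))
  expect_identical(unname(tools::md5sum(file.path(d1, m1$path))),
                   unname(tools::md5sum(file.path(d2, m2$path))))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("FGV targets follow the composition identity with zero noise", {
  cfg <- smallCohortConfig(10, fatFraction = 0.4, stromaFraction = 0.5,
                           epiFraction = 0.1, fgvNoiseSd = 0,
                           compositionSd = 0, epiFractionSd = 0,
                           localizedSd = 0, rngSeed = 5)
  d <- file.path(tempdir(), "coh-id")
  meta <- generateCohort(cfg, d)
  expect_true(all(meta$global_fgv == 60))
  expect_true(all(meta$localized_fgv == 60))
  pat <- attr(meta, "patients")
  expect_equal(pat$global_fgv, 100 * (1 - pat$fat))
  unlink(d, recursive = TRUE)
})

test_that("patient-level split and diagnosis quotas are exact", {
  cfg <- smallCohortConfig(100, rngSeed = 3)
  d <- file.path(tempdir(), "coh-split")
  meta <- generateCohort(cfg, d)
  pat <- attr(meta, "patients")
  expect_equal(sum(pat$split == "train"), 69)
  expect_equal(sum(pat$split == "test"), 31)
  unlink(d, recursive = TRUE)

  cfg2 <- smallCohortConfig(200, invasiveFraction = 0.2, rngSeed = 3)
  d2 <- file.path(tempdir(), "coh-quota")
  meta2 <- generateCohort(cfg2, d2)
  pat2 <- attr(meta2, "patients")
  expect_equal(sum(pat2$diagnosis == "invasive"), 40)
  expect_equal(sum(pat2$diagnosis == "insitu"),
               round(cfg2@insituFraction * 200))
  unlink(d2, recursive = TRUE)
})

test_that("tiny cohorts are refused and the CSV has the documented header", {
  expect_error(generateCohort(smallCohortConfig(5), tempfile()),
               "at least 10")
  cfg <- smallCohortConfig(10, rngSeed = 8)
  d <- file.path(tempdir(), "coh-hdr")
  generateCohort(cfg, d)
  hdr <- names(read.csv(file.path(d, "cohort.csv"), nrows = 1))
  expect_identical(hdr, c("patient_id", "slide_id", "path", "split",
                          "diagnosis", "global_fgv", "localized_fgv",
                          "bmi", "menopause"))
  unlink(d, recursive = TRUE)
})

test_that("worst diagnosis follows the severity order", {
  expect_equal(worstDiagnosis(c("proliferative", "invasive", "atypia")),
               "invasive")
  expect_equal(worstDiagnosis(c("benign_nonproliferative", "atypia")),
               "atypia")
  expect_equal(worstDiagnosis("proliferative"), "proliferative")
})
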