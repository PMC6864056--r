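#' Create a synthetic-cohort configuration
#'
#' Defines the conditions under which the synthetic label-map cohort is
#' generated. Defaults emulate a diagnostic core-biopsy study population:
#' mean tissue composition fat/stroma/epithelium = 0.62/0.28/0.10 (so the
#' cohort's median dense fraction sits near the 34-40% fibroglandular-volume
#' range typical of screening populations), wide patient-to-patient
#' composition spread, small slide-to-slide jitter, and a diagnosis mix of
#' 15% invasive and 8% in-situ. Invasive patients differ from benign ones
#' only in epithelial spatial organization (coalescent vs dispersed region
#' placement), not in total epithelial fraction.
#'
#' @param imageHeight,imageWidth map size in pixels.
#' @param micronsPerPixel physical pixel size in micrometres.
#' @param nPatients number of patients (>= 10 for cohort generation).
#' @param slidesPerPatient label maps per patient.
#' @param fatFraction,stromaFraction,epiFraction mean proportions of the
#'   tissue area; must sum to 1.
#' @param backgroundFraction proportion of the image that is background glass.
#' @param epiRegionCountMean mean number of epithelial regions per slide.
#' @param epiRegionAreaMean nominal epithelial region area in pixels; sets
#'   the minimum blob size (composition and region count take precedence in
#'   determining realized areas).
#' @param epiEccentricityMean mean eccentricity of stamped regions, in [0,1).
#' @param clusteringMode spatial point process used to place epithelial
#'   regions: `"dispersed"` (hard-core minimum-distance), `"clustered"`
#'   (parent-offspring Thomas-style) or `"coalescent"` (few large merging
#'   blobs).
#' @param fgvNoiseSd measurement noise of the fibroglandular-volume targets,
#'   in percentage points.
#' @param invasiveFraction,insituFraction quota proportions of invasive and
#'   in-situ patients (assigned exactly, not by Bernoulli draws).
#' @param compositionSd patient-level SD of the dense (stroma+epithelium)
#'   tissue fraction.
#' @param epiFractionSd patient-level SD of the epithelial tissue fraction.
#' @param slideJitterSd slide-level composition jitter around the patient
#'   draw, in percentage points.
#' @param localizedSd SD of the localized-composition perturbation, in
#'   percentage points.
#' @param rngSeed integer seed; the same seed reproduces the cohort
#'   byte-for-byte.
#' @return A [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(nPatients = 20, imageHeight = 96, imageWidth = 96)
#' cfg
#' @export
simulationConfig <- function(imageHeight = 256, imageWidth = 256,
                             micronsPerPixel = 0.5,
                             nPatients = 580, slidesPerPatient = 2,
                             fatFraction = 0.62, stromaFraction = 0.28,
                             epiFraction = 0.10, backgroundFraction = 0.1,
                             epiRegionCountMean = 12,
                             epiRegionAreaMean = 480,
                             epiEccentricityMean = 0.7,
                             clusteringMode = "dispersed",
                             fgvNoiseSd = 5, invasiveFraction = 0.15,
                             insituFraction = 0.08,
                             compositionSd = 0.18, epiFractionSd = 0.03,
                             slideJitterSd = 2, localizedSd = 4,
                             rngSeed = 1) {
  new("SimulationConfig",
      imageHeight = imageHeight, imageWidth = imageWidth,
      micronsPerPixel = micronsPerPixel, nPatients = nPatients,
      slidesPerPatient = slidesPerPatient, fatFraction = fatFraction,
      stromaFraction = stromaFraction, epiFraction = epiFraction,
      backgroundFraction = backgroundFraction,
      epiRegionCountMean = epiRegionCountMean,
      epiRegionAreaMean = epiRegionAreaMean,
      epiEccentricityMean = epiEccentricityMean,
      clusteringMode = clusteringMode, fgvNoiseSd = fgvNoiseSd,
      invasiveFraction = invasiveFraction, insituFraction = insituFraction,
      compositionSd = compositionSd, epiFractionSd = epiFractionSd,
      slideJitterSd = slideJitterSd, localizedSd = localizedSd,
      rngSeed = rngSeed)
}

# superellipse tissue mask covering (1 - backgroundFraction) of the image
tissueMaskFor <- function(H, W, backgroundFraction) {
  f <- 1 - backgroundFraction
  if (f >= 1 - 1e-12) return(matrix(TRUE, H, W))
  # coverage factor of a superellipse within its bounding box
  cov <- function(p) gamma(1 + 1 / p)^2 / gamma(1 + 2 / p)
  p <- NULL
  for (cand in c(2, 4, 8, 16, 32)) if (cov(cand) >= f) { p <- cand; break }
  if (is.null(p)) p <- 64
  sc <- min(1, sqrt(f / cov(p)))
  ry <- sc * (H - 1) / 2; rx <- sc * (W - 1) / 2
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  yy <- abs((seq_len(H) - 1 - cy) / ry)^p
  xx <- abs((seq_len(W) - 1 - cx) / rx)^p
  outer(yy, xx, "+") <= 1
}

# smooth Gaussian random field (FFT convolution, toroidal kernel); used only
# through its within-mask ranks, so normalization is irrelevant
smoothField <- function(H, W, sigma = 6) {
  noise <- matrix(rnorm(H * W), H, W)
  kr <- stats::dnorm(pmin(0:(H - 1), H - (0:(H - 1))), sd = sigma)
  kc <- stats::dnorm(pmin(0:(W - 1), W - (0:(W - 1))), sd = sigma)
  kern <- outer(kr, kc)
  Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE))
}

# 8-neighborhood dilation restricted to the grid
dilate8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-H, ]
  out[-H, ] <- out[-H, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -W]
  out[, -W] <- out[, -W] | m[, -1]
  out[-1, -1] <- out[-1, -1] | m[-H, -W]
  out[-H, -W] <- out[-H, -W] | m[-1, -1]
  out[-1, -W] <- out[-1, -W] | m[-H, -1]
  out[-H, -1] <- out[-H, -1] | m[-1, -W]
  out
}

# place region centers according to the clustering mode; returns N x 2 (r, c)
placeCenters <- function(mode, radii, tissueCoord, H, W) {
  N <- length(radii)
  centers <- matrix(NA_real_, N, 2)
  meanR <- mean(radii)
  pickTissue <- function() tissueCoord[sample.int(nrow(tissueCoord), 1L), ]
  # rejection placement against per-pair minimum distances; falls back to the
  # least-crowded candidate when the constraint cannot be met
  place <- function(i, propose, minDistVec) {
    bestCand <- propose(); bestSlack <- -Inf
    for (try in seq_len(200)) {
      cand <- if (try == 1L) bestCand else propose()
      if (i == 1L) return(cand)
      d <- sqrt((centers[seq_len(i - 1), 1] - cand[1])^2 +
                (centers[seq_len(i - 1), 2] - cand[2])^2)
      slack <- min(d - minDistVec)
      if (slack >= 0) return(cand)
      if (slack > bestSlack) { bestSlack <- slack; bestCand <- cand }
    }
    bestCand
  }
  # minimum center separation that keeps blob i clear of blobs 1..i-1
  touch <- function(i) 1.02 * (radii[seq_len(i - 1)] + radii[i]) + 1.5
  seedPoints <- function(P, minDist) {
    pts <- matrix(NA_real_, P, 2)
    for (p in seq_len(P)) {
      cand <- pickTissue()
      for (try in seq_len(200)) {
        if (p == 1L ||
            min(sqrt((pts[seq_len(p - 1), 1] - cand[1])^2 +
                     (pts[seq_len(p - 1), 2] - cand[2])^2)) >= minDist)
          break
        cand <- pickTissue()
      }
      pts[p, ] <- cand
    }
    pts
  }
  if (mode == "dispersed") {
    # hard-core with generous spacing: regions spread over the whole tissue
    for (i in seq_len(N))
      centers[i, ] <- place(i, pickTissue, touch(i) + 3 * meanR)
  } else if (mode == "clustered") {
    # Thomas-style parent-offspring: clumped but non-overlapping
    P <- max(1L, round(N / 4))
    parents <- seedPoints(P, 6 * meanR)
    for (i in seq_len(N)) {
      par <- parents[((i - 1L) %% P) + 1L, ]
      propose <- function() clamp(par + rnorm(2, sd = 2.5 * meanR),
                                  c(1, 1), c(H, W))
      centers[i, ] <- place(i, propose, touch(i))
    }
  } else {
    # coalescent: near-touching packs around one or two foci, so influence
    # zones inside the pack collapse onto the regions themselves and some
    # blobs merge into large components
    C <- if (N > 8) 2L else 1L
    foci <- seedPoints(C, 14 * meanR)
    for (i in seq_len(N)) {
      fc <- foci[((i - 1L) %% C) + 1L, ]
      s <- meanR * (0.8 + 0.45 * sqrt(i))
      propose <- function() clamp(fc + rnorm(2, sd = s), c(1, 1), c(H, W))
      centers[i, ] <- place(i, propose, touch(i))
    }
  }
  centers
}

# stamp one elliptical blob of the requested pixel area into epi (in place
# semantics via return), clipped to the tissue mask
stampEllipse <- function(epi, tissue, center, areaPx, ecc, theta) {
  H <- nrow(epi); W <- ncol(epi)
  q <- sqrt(1 - ecc^2)
  a <- sqrt(areaPx / (pi * q))   # semi-major
  b <- a * q
  r0 <- max(1L, floor(center[1] - a)); r1 <- min(H, ceiling(center[1] + a))
  c0 <- max(1L, floor(center[2] - a)); c1 <- min(W, ceiling(center[2] + a))
  if (r0 > r1 || c0 > c1) return(epi)
  rr <- r0:r1; cc <- c0:c1
  dy <- rr - center[1]; dx <- cc - center[2]
  u <- outer(dy * cos(theta), dx * sin(theta), "+")
  v <- outer(-dy * sin(theta), dx * cos(theta), "+")
  inside <- (u / a)^2 + (v / b)^2 <= 1
  epi[rr, cc] <- epi[rr, cc] | (inside & tissue[rr, cc])
  epi
}

#' Generate one synthetic tissue-class label map
#'
#' Builds a label map whose realized class composition tracks the requested
#' one to within a few percentage points and whose epithelial regions are
#' placed by the configured point process. Stroma and fat are carved out of
#' the non-epithelial tissue by thresholding a smooth random field, which
#' yields spatially coherent compartments at exact pixel quotas.
#'
#' @param config a [SimulationConfig-class]; supplies image geometry and the
#'   defaults for `patientState`.
#' @param patientState optional list with elements `composition` (named
#'   vector `fat`, `stroma`, `epi` summing to 1), `mode`, `countMean`,
#'   `eccMean` and optionally `background` (per-slide glass fraction);
#'   defaults are taken from `config`. This is the slide-level
#'   draw: tolerance of the realized composition (about 3 percentage
#'   points) is relative to it.
#' @param slideIndex index used in the slide identifier.
#' @param seed optional integer; when given, the map is generated under a
#'   private RNG stream seeded with it.
#' @return A [TissueMap-class].
#' @examples
#' cfg <- simulationConfig(imageHeight = 96, imageWidth = 96)
#' m <- generateTissueMap(cfg, seed = 7)
#' mean(tissueLabels(m) == 1) / mean(tissueLabels(m) > 0) # ~ epiFraction
#' @export
generateTissueMap <- function(config, patientState = NULL, slideIndex = 1L,
                              seed = NULL) {
  validObject(config)
  if (!is.null(seed))
    return(withSeed(seed, generateTissueMap(config, patientState, slideIndex)))
  if (is.null(patientState))
    patientState <- list(
      composition = c(fat = config@fatFraction,
                      stroma = config@stromaFraction,
                      epi = config@epiFraction),
      mode = config@clusteringMode,
      countMean = config@epiRegionCountMean,
      eccMean = config@epiEccentricityMean)
  comp <- patientState$composition
  if (any(comp < -1e-9) || comp[["epi"]] > 1 + 1e-9)
    stop(errorCondition("requested epithelial area exceeds available tissue",
                        class = c("infeasibleCompositionError", "error",
                                  "condition")))
  H <- as.integer(config@imageHeight); W <- as.integer(config@imageWidth)
  bg <- if (is.null(patientState$background)) config@backgroundFraction else
    patientState$background
  tissue <- tissueMaskFor(H, W, bg)
  Tpx <- sum(tissue)
  epiTarget <- round(comp[["epi"]] * Tpx)
  if (epiTarget > Tpx)
    stop(errorCondition("requested epithelial area exceeds available tissue",
                        class = c("infeasibleCompositionError", "error",
                                  "condition")))
  epi <- matrix(FALSE, H, W)
  if (epiTarget > 0) {
    N <- max(1L, rpois(1L, patientState$countMean))
    minArea <- max(25, 0.15 * config@epiRegionAreaMean)
    areas <- rgamma(N, shape = 6)
    areas <- pmax(areas / sum(areas) * epiTarget, minArea)
    areas <- areas / sum(areas) * epiTarget
    eccs <- clamp(rnorm(N, patientState$eccMean, 0.1), 0, 0.95)
    thetas <- runif(N, 0, pi)
    radii <- sqrt(areas / (pi * sqrt(1 - eccs^2)))
    tc <- which(tissue, arr.ind = TRUE)
    centers <- placeCenters(patientState$mode, radii, tc, H, W)
    for (i in seq_len(N))
      epi <- stampEllipse(epi, tissue, centers[i, ], areas[i], eccs[i],
                          thetas[i])
    # compensate boundary clipping / overlap by growing existing regions
    for (iter in seq_len(100)) {
      deficit <- epiTarget - sum(epi)
      if (deficit <= max(0.01 * Tpx, 16)) break
      ring <- which(tissue & !epi & dilate8(epi))
      if (length(ring) == 0L) break
      if (length(ring) > deficit) ring <- sample(ring, deficit)
      epi[ring] <- TRUE
    }
  }
  labels <- matrix(0L, H, W)
  labels[epi] <- 1L
  rest <- which(tissue & !epi)
  stromaN <- min(length(rest), round(comp[["stroma"]] * Tpx))
  if (stromaN > 0 && length(rest) > 0) {
    fld <- smoothField(H, W)
    ord <- order(fld[rest])
    labels[rest[ord[seq_len(stromaN)]]] <- 2L
    if (stromaN < length(rest)) labels[rest[ord[-seq_len(stromaN)]]] <- 3L
  } else if (length(rest) > 0) {
    labels[rest] <- 3L
  }
  TissueMap(labels, micronsPerPixel = config@micronsPerPixel,
            slideId = sprintf("s%03d", as.integer(slideIndex)))
}

# worst-first severity order used for patient-level diagnosis
diagnosisLevels <- c("benign_nonproliferative", "proliferative", "atypia",
                     "insitu", "invasive")

#' Generate a synthetic cohort of label maps with known density targets
#'
#' Draws per-patient tissue compositions, ties the fibroglandular-volume
#' targets to them by construction (`global_fgv` = 100 x dense-tissue
#' fraction + Gaussian noise, clipped to \[0, 100\]; `localized_fgv` the same
#' from a locally perturbed composition), assigns diagnoses by exact quota,
#' and writes one PNG label map per slide plus a slide-level metadata CSV.
#' Invasive patients are generated with coalescent epithelial organization
#' and enlarged regions; all others with dispersed organization at an
#' overlapping epithelial fraction, so diagnosis is encoded in spatial
#' arrangement rather than epithelial quantity.
#'
#' Patients are split 69%/31% into train/test at the patient level. The
#' whole cohort is a deterministic function of `rngSeed`.
#'
#' @param config a [SimulationConfig-class] with `nPatients >= 10`.
#' @param dir output directory; maps go to `dir/maps/`, the metadata table to
#'   `dir/cohort.csv` (columns `patient_id, slide_id, path, split, diagnosis,
#'   global_fgv, localized_fgv, bmi, menopause`; `path` is relative to
#'   `dir`).
#' @return The slide-level metadata data.frame, invisibly, with the
#'   patient-level draw table attached as attribute `"patients"`.
#' @export
generateCohort <- function(config, dir) {
  validObject(config)
  n <- as.integer(config@nPatients)
  if (n < 10L)
    stop("nPatients must be at least 10 for a meaningful cohort")
  dir.create(file.path(dir, "maps"), recursive = TRUE, showWarnings = FALSE)
  withSeed(config@rngSeed, {
    # diagnosis quotas (exact counts, shuffled across patients)
    nInv <- round(config@invasiveFraction * n)
    nIns <- round(config@insituFraction * n)
    nRem <- n - nInv - nIns
    nAty <- round(0.09 * nRem); nPro <- round(0.48 * nRem)
    diag <- sample(rep(diagnosisLevels,
                       c(nRem - nAty - nPro, nPro, nAty, nIns, nInv)))
    # 69/31 patient-level split
    nTrain <- round(0.69 * n)
    split <- character(n)
    split[sample.int(n)] <- rep(c("train", "test"), c(nTrain, n - nTrain))
    meanDense <- config@stromaFraction + config@epiFraction
    rows <- vector("list", n * as.integer(config@slidesPerPatient))
    pat <- vector("list", n)
    k <- 0L
    for (i in seq_len(n)) {
      dense <- clamp(rnorm(1, meanDense, config@compositionSd), 0.03, 0.97)
      epi <- clamp(rnorm(1, config@epiFraction, config@epiFractionSd),
                   0.01, 0.6 * dense)
      comp <- c(fat = 1 - dense, stroma = dense - epi, epi = epi)
      gfgv <- clamp(100 * dense + rnorm(1, 0, config@fgvNoiseSd), 0, 100)
      denseLoc <- clamp(dense + rnorm(1, 0, config@localizedSd / 100),
                        0.01, 0.99)
      lfgv <- clamp(100 * denseLoc + rnorm(1, 0, config@fgvNoiseSd), 0, 100)
      invasive <- diag[i] == "invasive"
      # invasive: coalescent organization; merging of the near-touching pack
      # yields enlarged epithelial components at the same epithelial fraction
      state <- list(
        composition = comp,
        mode = if (invasive) "coalescent" else config@clusteringMode,
        countMean = config@epiRegionCountMean,
        eccMean = config@epiEccentricityMean)
      bmi <- round(clamp(26.7 + 10 * (meanDense - dense) + rnorm(1, 0, 4),
                         16, 55), 1)
      menopause <- if (runif(1) < 0.42) "post" else "pre"
      pid <- sprintf("p%04d", i)
      pat[[i]] <- data.frame(
        patient_id = pid, diagnosis = diag[i], split = split[i],
        fat = comp[["fat"]], stroma = comp[["stroma"]], epi = comp[["epi"]],
        global_fgv = gfgv, localized_fgv = lfgv, bmi = bmi,
        menopause = menopause, clustering_mode = state$mode)
      for (s in seq_len(as.integer(config@slidesPerPatient))) {
        denseS <- clamp(dense + rnorm(1, 0, config@slideJitterSd / 100),
                        0.02, 0.98)
        epiS <- clamp(epi + rnorm(1, 0, config@slideJitterSd / 200),
                      0.005, 0.7 * denseS)
        stateS <- state
        stateS$composition <- c(fat = 1 - denseS, stroma = denseS - epiS,
                                epi = epiS)
        # biopsy sections differ in size: vary the glass fraction per slide
        # so absolute tissue amounts are not collinear with normalized ones
        stateS$background <- clamp(rnorm(1, config@backgroundFraction, 0.08),
                                   0.02, 0.5)
        map <- generateTissueMap(config, stateS, slideIndex = s)
        sid <- sprintf("%s_s%d", pid, s)
        rel <- file.path("maps", paste0(sid, ".png"))
        writeTissueMap(map, file.path(dir, rel))
        k <- k + 1L
        rows[[k]] <- data.frame(
          patient_id = pid, slide_id = sid, path = rel, split = split[i],
          diagnosis = diag[i], global_fgv = gfgv, localized_fgv = lfgv,
          bmi = bmi, menopause = menopause)
      }
    }
    meta <- do.call(rbind, rows)
    write.csv(meta, file.path(dir, "cohort.csv"), row.names = FALSE)
    attr(meta, "patients") <- do.call(rbind, pat)
    invisible(meta)
  })
}

#' Worst diagnosis across biopsies
#'
#' Severity order: benign non-proliferative < proliferative < atypia <
#' in-situ < invasive.
#'
#' @param x character vector of diagnosis categories.
#' @return the single worst category.
#' @export
worstDiagnosis <- function(x) {
  diagnosisLevels[max(match(x, diagnosisLevels))]
}
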