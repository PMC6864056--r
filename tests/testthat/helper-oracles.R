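# Independent brute-force oracles used to validate the fast implementations.
# These deliberately share no code with the package internals.

# Exhaustive area-Voronoi: for every tissue pixel, measure the Euclidean
# distance to every region's pixel set; assign the nearest region, ties to
# the lowest region label.
bruteVoronoi <- function(compImage, tissueMask) {
  H <- nrow(compImage); W <- ncol(compImage)
  K <- max(compImage)
  tIdx <- which(tissueMask)
  tr <- (tIdx - 1) %% H; tc <- (tIdx - 1) %/% H
  best <- rep(Inf, length(tIdx))
  lab <- integer(length(tIdx))
  for (k in seq_len(K)) {
    rIdx <- which(compImage == k)
    rr <- (rIdx - 1) %% H; rc <- (rIdx - 1) %/% H
    d2 <- outer(tr, rr, function(a, b) (a - b)^2) +
          outer(tc, rc, function(a, b) (a - b)^2)
    dmin <- apply(d2, 1, min)
    upd <- dmin < best  # strict: earlier (lower) label keeps ties
    best[upd] <- dmin[upd]
    lab[upd] <- k
  }
  out <- matrix(0L, H, W)
  out[tIdx] <- lab
  out
}

# O(n^4) Delaunay oracle: a triangle belongs to the triangulation iff its
# circumcircle contains no other point strictly inside; edges are the union
# of triangle edges (n >= 3, general position).
bruteDelaunayEdges <- function(x, y) {
  n <- length(x)
  if (n < 2) return(matrix(integer(), 0, 2))
  if (n == 2) return(matrix(c(1L, 2L), 1, 2))
  edges <- matrix(integer(), 0, 2)
  addEdge <- function(e, i, j) {
    ij <- sort(c(i, j))
    if (!any(e[, 1] == ij[1] & e[, 2] == ij[2])) rbind(e, ij) else e
  }
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) next  # collinear: no circumcircle
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    others <- setdiff(seq_len(n), c(i, j, k))
    inside <- ((x[others] - ux)^2 + (y[others] - uy)^2) < r2 * (1 - 1e-12)
    if (!any(inside)) {
      edges <- addEdge(edges, i, j)
      edges <- addEdge(edges, i, k)
      edges <- addEdge(edges, j, k)
    }
  }
  edges
}

bruteDelaunayDegrees <- function(x, y) {
  e <- bruteDelaunayEdges(x, y)
  tabulate(c(e), nbins = length(x))
}

# brute-force second-central-moment eccentricity of a pixel set
bruteEccentricity <- function(rows, cols) {
  n <- length(rows)
  mu20 <- sum((rows - mean(rows))^2) / n
  mu02 <- sum((cols - mean(cols))^2) / n
  mu11 <- sum((rows - mean(rows)) * (cols - mean(cols))) / n
  ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2), symmetric = TRUE)$values
  if (ev[1] <= 0) return(0)
  sqrt(max(1 - ev[2] / ev[1], 0))
}

# independent sort-based summaries (linear-interpolation quartiles)
bruteSummary <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0) return(c(mean = 0, median = 0, sd = 0, iq = 0, max = 0))
  qat <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  c(mean = sum(x) / n,
    median = qat(0.5),
    sd = if (n > 1) sqrt(sum((x - sum(x) / n)^2) / (n - 1)) else 0,
    iq = qat(0.75) - qat(0.25),
    max = x[n])
}

# manual Spearman rank correlation (average ranks for ties)
bruteSpearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  num / den
}

# random small label map with a handful of square/rectangular epithelial
# regions, used by the Voronoi oracle-equivalence checks
randomSmallMap <- function(seed, H = 64, W = 64, maxRegions = 6) {
  set.seed(seed)
  lab <- matrix(sample(c(0L, 2L, 3L), H * W, replace = TRUE,
                       prob = c(0.15, 0.5, 0.35)), H, W)
  nReg <- sample.int(maxRegions, 1)
  for (i in seq_len(nReg)) {
    h <- sample(2:6, 1); w <- sample(2:6, 1)
    r0 <- sample.int(H - h, 1); c0 <- sample.int(W - w, 1)
    lab[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- 1L
  }
  HistoDensity::TissueMap(lab, micronsPerPixel = 0.5,
                          slideId = paste0("rand", seed))
}

# shared default synthetic cohort for the simulation-scale checks; built on
# first use and cached for the remainder of the test run
.cohortCache <- new.env(parent = emptyenv())
defaultCohort <- function() {
  if (!is.null(.cohortCache$cohort)) return(.cohortCache$cohort)
  dir <- file.path(tempdir(), "histodensity-default-cohort")
  cfg <- HistoDensity::simulationConfig(rngSeed = 20240917)
  meta <- HistoDensity::generateCohort(cfg, dir)
  slideFeat <- HistoDensity::extractFeaturesCohort(
    meta, dir, micronsPerPixel = cfg@micronsPerPixel)
  cohort <- HistoDensity::buildCohortTable(
    HistoDensity::aggregateCohort(slideFeat), meta)
  .cohortCache$cohort <- cohort
  cohort
}
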