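# Build the shipped synthetic fixture map and its frozen 37-feature vector.
# Every quantity is computed here with the independent brute-force oracles
# (tests/testthat/helper-oracles.R), NOT with the package's fast paths, so
# the golden file is a true cross-check. Run once from the repo root:
#   Rscript tools/make_fixture.R

source("tests/testthat/helper-oracles.R")

H <- W <- 64L
mpp <- 0.5
lab <- matrix(3L, H, W)                      # fat everywhere ...
lab[, seq_len(32)] <- 2L                     # ... stroma in the left half
lab[c(1:2, 63:64), ] <- 0L                   # 2-px glass frame
lab[, c(1:2, 63:64)] <- 0L

# three epithelial regions, listed deterministically
# A: 12 x 18 rectangle
lab[6:17, 5:22] <- 1L
# B: disc of radius 9 centred at (44, 14) (1-based)
for (r in 1:H) for (c in 1:W)
  if ((r - 44)^2 + (c - 14)^2 <= 81) lab[r, c] <- 1L
# C: L-shape
lab[10:39, 48:53] <- 1L
lab[34:39, 29:53] <- 1L

stopifnot(all(lab[c(1:2, 63:64), ] == 0L))

# ---- oracle feature computation ------------------------------------------
# independent 8-connected labelling, scanning column-major for canonical ids
oracleLabel <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0L, H, W)
  k <- 0L
  for (cc in 1:W) for (rr in 1:H) {
    if (!mask[rr, cc] || out[rr, cc] != 0L) next
    k <- k + 1L
    frontier <- matrix(c(rr, cc), 1)
    out[rr, cc] <- k
    while (nrow(frontier) > 0) {
      nxt <- NULL
      for (i in seq_len(nrow(frontier))) {
        for (dr in -1:1) for (dc in -1:1) {
          nr <- frontier[i, 1] + dr; nc <- frontier[i, 2] + dc
          if (nr >= 1 && nr <= H && nc >= 1 && nc <= W &&
              mask[nr, nc] && out[nr, nc] == 0L) {
            out[nr, nc] <- k
            nxt <- rbind(nxt, c(nr, nc))
          }
        }
      }
      frontier <- if (is.null(nxt)) matrix(numeric(), 0, 2) else nxt
    }
  }
  out
}

comp <- oracleLabel(lab == 1L)
K <- max(comp)
stopifnot(K == 3)
tissue <- lab > 0L
Tpx <- sum(tissue)

# globals
counts <- tabulate(lab + 1L, nbins = 4L)
feat <- c(
  fat_amount = counts[4] * mpp^2,
  fat_amount_norm = 100 * counts[4] / Tpx,
  stroma_amount = counts[3] * mpp^2,
  stroma_amount_norm = 100 * counts[3] / Tpx,
  epi_amount = counts[2] * mpp^2,
  epi_amount_norm = 100 * counts[2] / Tpx)

# morphology (min area 50 um^2 = 200 px: all three regions survive)
areas <- numeric(K); ecc <- numeric(K); cr <- numeric(K); cc <- numeric(K)
for (k in 1:K) {
  idx <- which(comp == k, arr.ind = TRUE)
  stopifnot(nrow(idx) * mpp^2 >= 50)
  rows0 <- idx[, 1] - 1; cols0 <- idx[, 2] - 1
  areas[k] <- nrow(idx) * mpp^2
  ecc[k] <- bruteEccentricity(rows0, cols0)
  cr[k] <- mean(rows0); cc[k] <- mean(cols0)
}
feat <- c(feat, n_epi_regions = K,
          setNames(bruteSummary(areas), paste0("epi_area_",
            c("mean", "median", "sd", "iq", "max"))),
          setNames(bruteSummary(ecc), paste0("epi_ecc_",
            c("mean", "median", "sd", "iq", "max"))))

# area-Voronoi (brute force) + ratios
vor <- bruteVoronoi(comp, tissue)
va <- tabulate(vor[vor > 0], nbins = K) * mpp^2
stopifnot(sum(va) == Tpx * mpp^2)
rev_ <- areas / va
ren <- ifelse(va - areas > 0, areas / (va - areas), NA_real_)
feat <- c(feat,
          setNames(bruteSummary(va), paste0("voronoi_area_",
            c("mean", "median", "sd", "iq", "max"))),
          setNames(bruteSummary(rev_), paste0("ratio_epi_voronoi_",
            c("mean", "median", "sd", "iq", "max"))),
          setNames(bruteSummary(ren), paste0("ratio_epi_nonepi_",
            c("mean", "median", "sd", "iq", "max"))))

# Delaunay degrees of the three centroids (x = col, y = row)
deg <- bruteDelaunayDegrees(cc, cr)
feat <- c(feat,
          setNames(bruteSummary(deg), paste0("delaunay_neighbors_",
            c("mean", "median", "sd", "iq", "max"))))

stopifnot(length(feat) == 37)

dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
# plain-text map (one CSV row per image row) so the fixture is fully
# inspectable and survives source-only distribution
write.table(lab, "inst/extdata/synthetic_fixture_map64.csv", sep = ",",
            row.names = FALSE, col.names = FALSE)
write.csv(data.frame(feature = names(feat), value = unname(feat)),
          "inst/extdata/synthetic_fixture_features.csv", row.names = FALSE)
cat("fixture written;", K, "regions; tissue px:", Tpx, "\n")
print(round(feat, 4))
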