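#' Read a tissue-class label map from PNG or TIFF
#'
#' Label maps are stored as 8-bit single-channel images whose pixel values are
#' the tissue codes 0 (background), 1 (epithelium), 2 (stroma), 3 (fat).
#'
#' @param path path to a `.png` or `.tif`/`.tiff` file.
#' @param micronsPerPixel physical pixel size in micrometres.
#' @param slideId identifier; defaults to the file name without extension.
#' @return A [TissueMap-class].
#' @export
readTissueMap <- function(path, micronsPerPixel = 0.5,
                          slideId = sub("\\.[^.]+$", "", basename(path))) {
  ext <- tolower(sub(".*\\.", "", path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF maps requires the 'tiff' package")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  labels <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  TissueMap(labels, micronsPerPixel = micronsPerPixel, slideId = slideId)
}

#' Write a tissue-class label map as 8-bit grayscale PNG
#'
#' @param map a [TissueMap-class].
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
writeTissueMap <- function(map, path) {
  stopifnot(is(map, "TissueMap"))
  png::writePNG(map@labels / 255, target = path)
  invisible(path)
}
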