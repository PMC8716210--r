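# Image and report I/O. OCT exports are treated as linear: 8-bit containers
# divide by 255, 16-bit by 65535, no gamma handling. RGB inputs (gray scans
# saved as color) are collapsed by unweighted channel mean.

#' Read a grayscale OCT B-scan image
#'
#' Reads a PNG, TIFF or JPEG file and maps its integer range linearly to
#' \[0, 1\]. RGB images are converted by the unweighted channel mean; an
#' alpha channel, if present, is ignored.
#'
#' @param path path to a PNG, TIFF or JPEG file.
#' @return A [GrayImage-class].
#' @examples
#' tmp <- tempfile(fileext = ".png")
#' png::writePNG(matrix(runif(64), 8, 8), tmp)
#' img <- readGrayImage(tmp)
#' @export
readGrayImage <- function(path) {
  if (!file.exists(path)) mhStop("io_error", sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    mhStop("format_error",
           sprintf("unsupported format '%s' (PNG, TIFF or JPEG expected)", ext))
  )
  if (is.list(arr)) arr <- arr[[1L]]  # multi-page TIFF: first page
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3L]
    ch <- if (nch >= 3L) 1:3 else seq_len(nch)  # drop alpha
    arr <- apply(arr[, , ch, drop = FALSE], c(1, 2), mean)
  }
  if (length(arr) == 0L || nrow(arr) < 3L || ncol(arr) < 3L)
    mhStop("validation_error", "image must be at least 3 x 3 pixels")
  GrayImage(clamp01(arr))
}

#' Write a binary mask as an 8-bit PNG
#'
#' Writes values \{0, 1\} as \{0, 255\}; reading the file back and
#' re-binarizing reproduces the mask bit-exactly.
#'
#' @param mask a [BinaryMask-class].
#' @param path output PNG path; the parent directory must exist.
#' @return Invisibly, `path`.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  if (!dir.exists(dirname(path)))
    mhStop("io_error", sprintf("directory does not exist: %s", dirname(path)))
  png::writePNG(mask@pixels, path)
  invisible(path)
}

#' Write an evaluation report (JSON) and optional feature table (CSV)
#'
#' The JSON report carries the per-image metric records plus a mean row;
#' for the mean, missing values (e.g. sensitivity of truth-empty images)
#' are excluded rather than averaged in as zero. Accuracy here is
#' pixel-wise agreement between mask and ground truth.
#'
#' @param metrics data.frame of per-image metric records (one row per
#'   image) as produced by [metricsFromCounts()] / [evaluateMasks()].
#' @param path output JSON path.
#' @param features optional data.frame of per-image hole features, written
#'   as CSV next to `path` (same name, `.csv` extension).
#' @return Invisibly, `path`.
#' @export
writeReport <- function(metrics, path, features = NULL) {
  if (is.null(metrics) || nrow(as.data.frame(metrics)) == 0L)
    mhStop("validation_error", "no metric records to report")
  metrics <- as.data.frame(metrics)
  if (!dir.exists(dirname(path)))
    mhStop("io_error", sprintf("directory does not exist: %s", dirname(path)))
  num <- vapply(metrics, is.numeric, logical(1))
  meanRow <- lapply(metrics[num], function(x) mean(x, na.rm = TRUE))
  report <- list(
    n_images = nrow(metrics),
    accuracy_definition = "pixel-wise agreement with the ground-truth mask",
    images = metrics,
    mean = meanRow
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  if (!is.null(features)) {
    csv <- sub("\\.json$", ".csv", path)
    if (identical(csv, path)) csv <- paste0(path, ".csv")
    utils::write.csv(as.data.frame(features), csv, row.names = FALSE)
  }
  invisible(path)
}
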