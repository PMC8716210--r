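# End-to-end orchestration: preprocess -> edges + thresholds -> band ->
# fovea -> hole extraction -> refinement. Fully deterministic given
# (image, config).

#' Default pipeline configuration
#'
#' Nested list mirroring the CLI/config-file keys. Notable defaults:
#' 224 x 224 working size; 5 x 5 adaptive denoise window with estimated
#' noise variance; edge map at 0.2 of the maximum gradient magnitude;
#' Otsu thresholding with k = 3 (4 classes: vitreous, inner retina, outer
#' retina, RPE band — the minimum that isolates a hypo-reflective hole
#' inside a bright band); candidate filters minArea = 25 px and
#' minEdgeSupport = 0.1; fovea score decay width/8.
#'
#' @param ... named overrides for any top-level group, e.g.
#'   `mhConfig(threshold = list(k = 2))` (partial lists are merged).
#' @return Nested configuration list.
#' @export
mhConfig <- function(...) {
  cfg <- list(
    preprocess = list(targetSize = c(224L, 224L), window = 5L,
                      noiseVariance = NA_real_, logDomain = FALSE),
    edges = list(relThreshold = 0.2),
    threshold = list(k = 3L, method = "otsu", bins = 256L, smoothWindow = 5L),
    segment = list(minArea = 25L, minEdgeSupport = 0.1, decayFrac = 1 / 8),
    verbose = FALSE
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Segment a macular hole in an OCT B-scan
#'
#' Runs the full hybrid pipeline: standardization and min-max intensity
#' normalization, adaptive speckle denoising, Sobel gradient edge
#' detection, multilevel thresholding (Otsu by default; the valley rule
#' falls back to Otsu when the smoothed histogram has too few modes),
#' retinal-band and foveal-pit localization, dark-component hole
#' extraction with edge support and fovea-proximity scoring, and
#' morphological mask refinement (clipped back to the band interior).
#'
#' @param img a [GrayImage-class] or a path to a PNG/TIFF/JPEG file.
#' @param config configuration list from [mhConfig()].
#' @return A [HoleSegmentation-class]; `holeMask()` is all-zero when no
#'   hole was detected.
#' @examples
#' ph <- generatePhantom(PhantomSpec(seed = 7))
#' seg <- segmentHole(ph$image)
#' seg
#' @export
segmentHole <- function(img, config = mhConfig()) {
  t0 <- as.numeric(Sys.time())
  if (is.character(img)) img <- readGrayImage(img)
  stopifnot(is(img, "GrayImage"))
  v <- config$verbose

  ts <- config$preprocess$targetSize
  std <- standardizeImage(img, ts[1L], ts[2L])
  den <- adaptiveDenoise(std,
    DenoiseParams(config$preprocess$window, config$preprocess$noiseVariance),
    logDomain = isTRUE(config$preprocess$logDomain))
  stageLog(v, "preprocess", t0, sprintf("size %dx%d window %d",
           ts[1L], ts[2L], config$preprocess$window))

  grad <- sobelGradients(den)
  emask <- edgeMap(grad, config$edges$relThreshold)
  stageLog(v, "edges", t0, sprintf("relThreshold %.2f, %d edge px",
           config$edges$relThreshold, sum(emask@pixels)))

  hist <- buildHistogram(den, config$threshold$bins)
  tset <- if (identical(config$threshold$method, "valley")) {
    tryCatch(valleyThresholds(hist, config$threshold$k,
                              config$threshold$smoothWindow),
             mhseg_insufficient_modes = function(e)
               otsuMultilevel(hist, config$threshold$k))
  } else {
    otsuMultilevel(hist, config$threshold$k)
  }
  cmap <- applyThresholds(den, tset)
  stageLog(v, "threshold", t0, sprintf("method %s levels %s", tset@method,
           paste(sprintf("%.3f", tset@levels), collapse = ",")))

  band <- detectRetinaBand(cmap)
  fovea <- locateFoveaCenter(band)
  stageLog(v, "band/fovea", t0, sprintf("fovea col %d", as.integer(fovea)))

  cands <- extractHoleCandidates(cmap, emask, band, fovea,
                                 minArea = config$segment$minArea,
                                 minEdgeSupport = config$segment$minEdgeSupport,
                                 decayFrac = config$segment$decayFrac)
  chosen <- selectHole(cands)
  h <- nrow(den@pixels); w <- ncol(den@pixels)
  if (is.null(chosen)) {
    mask <- BinaryMask(matrix(0, h, w))
  } else {
    mask <- refineMask(chosen@mask)
    # refinement must not leak outside the band interior
    rows <- matrix(seq_len(h), h, w)
    inside <- matrix(band@valid, h, w, byrow = TRUE) &
      rows > matrix(band@top, h, w, byrow = TRUE) &
      rows < matrix(band@bottom, h, w, byrow = TRUE)
    mask <- BinaryMask(mask@pixels * inside)
  }
  stageLog(v, "extract", t0, sprintf("%d candidate(s), %s", length(cands),
           if (is.null(chosen)) "no hole" else sprintf("area %d", sum(mask@pixels))))

  candTable <- if (length(cands)) data.frame(
    area = vapply(cands, function(x) x@area, integer(1)),
    centroidRow = vapply(cands, function(x) x@centroid[1L], numeric(1)),
    centroidCol = vapply(cands, function(x) x@centroid[2L], numeric(1)),
    edgeSupport = vapply(cands, function(x) x@edgeSupport, numeric(1)),
    score = vapply(cands, function(x) x@score, numeric(1))
  ) else data.frame()
  new("HoleSegmentation", mask = mask, foveaColumn = as.integer(fovea),
      band = band, chosen = chosen, allCandidates = cands,
      provenance = list(
        foveaOffCenter = isTRUE(attr(fovea, "offCenter")),
        thresholdLevels = tset@levels, thresholdMethod = tset@method,
        candidates = candTable, config = config))
}
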