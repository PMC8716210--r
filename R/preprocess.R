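# Geometry/intensity standardization and speckle suppression.
#
# The denoiser is a local-statistics adaptive (Lee/Wiener-type) minimum
# mean-square filter: out = m + gain * (in - m) with
# gain = max(0, v - vn) / v, where m and v are the window mean/variance
# and vn the noise variance. In flat regions (v <= vn) it returns the
# local mean; with vn = 0 it is the identity. This family is the standard
# OCT speckle choice and degrades gracefully to mean filtering.

#' Parameters of the adaptive speckle filter
#'
#' @slot window odd window side length in pixels (>= 3).
#' @slot noiseVariance noise variance in squared intensity units
#'   (>= 0); `NA` means "estimate from the image" via
#'   [estimateNoiseVariance()].
#' @export
setClass("DenoiseParams",
  representation(window = "integer", noiseVariance = "numeric"),
  validity = function(object) {
    w <- object@window
    if (w < 3L || w %% 2L == 0L) return("window must be odd and >= 3")
    if (!is.na(object@noiseVariance) && object@noiseVariance < 0)
      return("noiseVariance must be >= 0")
    TRUE
  })

#' Construct DenoiseParams
#'
#' @param window odd window side length (default 5).
#' @param noiseVariance noise variance; `NA` (default) to estimate.
#' @return A [DenoiseParams-class] object.
#' @export
DenoiseParams <- function(window = 5L, noiseVariance = NA_real_) {
  new("DenoiseParams", window = as.integer(window),
      noiseVariance = as.numeric(noiseVariance))
}

#' Standardize a B-scan to the working geometry and intensity range
#'
#' Resizes with bilinear interpolation to the target shape (the pipeline
#' default is 224 x 224) and min-max rescales the intensities to span
#' \[0, 1\]. A constant image maps to all zeros.
#'
#' @param img a [GrayImage-class].
#' @param targetHeight,targetWidth target dimensions (>= 3).
#' @return A [GrayImage-class] of the target shape.
#' @export
standardizeImage <- function(img, targetHeight = 224L, targetWidth = 224L) {
  stopifnot(is(img, "GrayImage"))
  if (targetHeight < 3L || targetWidth < 3L)
    mhStop("validation_error", "target dimensions must be >= 3")
  px <- img@pixels
  if (nrow(px) != targetHeight || ncol(px) != targetWidth) {
    # EBImage's first array dimension is our row dimension; no transpose needed.
    px <- EBImage::imageData(EBImage::resize(px, w = targetHeight,
                                             h = targetWidth,
                                             filter = "bilinear"))
  }
  rng <- range(px)
  px <- if (rng[2] > rng[1]) (px - rng[1]) / (rng[2] - rng[1])
        else matrix(0, nrow(px), ncol(px))
  GrayImage(clamp01(px))
}

#' Estimate the noise variance from background-dominated tiles
#'
#' Tiles the image into non-overlapping windows, computes the intensity
#' variance of each tile and returns the mean variance over the
#' lowest-variance decile of tiles. In a B-scan the lowest-variance tiles
#' are vitreous/background, so this is a background-dominated (slightly
#' conservative) estimate of the noise floor.
#'
#' @param img a [GrayImage-class].
#' @param tile tile side length in pixels (default 16; reduced for small
#'   images).
#' @return Non-negative noise variance estimate (0 for a constant image).
#' @export
estimateNoiseVariance <- function(img, tile = 16L) {
  stopifnot(is(img, "GrayImage"))
  px <- img@pixels
  tile <- max(2L, min(as.integer(tile), nrow(px), ncol(px)))
  nr <- nrow(px) %/% tile
  nc <- ncol(px) %/% tile
  if (nr < 1L || nc < 1L) return(0)
  v <- numeric(nr * nc)
  idx <- 1L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      block <- px[(i - 1L) * tile + seq_len(tile), (j - 1L) * tile + seq_len(tile)]
      v[idx] <- stats::var(as.vector(block))
      idx <- idx + 1L
    }
  }
  keep <- max(1L, ceiling(length(v) / 10))
  mean(sort(v)[seq_len(keep)])
}

#' Adaptive local-statistics speckle denoising
#'
#' Applies the Lee/Wiener-type minimum mean-square filter described above,
#' with replicate padding for the local statistics (avoiding dark halos at
#' the scan borders) and clipping of the result to \[0, 1\]. With
#' `logDomain = TRUE` the filter runs on `log(img + eps)` and the result is
#' exponentiated back, which matches multiplicative speckle more closely;
#' the default additive domain keeps the stage monotone in intensity.
#'
#' @param img a [GrayImage-class].
#' @param params a [DenoiseParams-class]; an `NA` noise variance is
#'   estimated with [estimateNoiseVariance()].
#' @param logDomain apply the filter in the log-intensity domain.
#' @return A denoised [GrayImage-class] of the same shape.
#' @export
adaptiveDenoise <- function(img, params = DenoiseParams(), logDomain = FALSE) {
  stopifnot(is(img, "GrayImage"), is(params, "DenoiseParams"))
  px <- img@pixels
  w <- params@window
  if (w > min(dim(px)))
    mhStop("validation_error", "denoise window larger than the image")
  vn <- params@noiseVariance
  if (isTRUE(logDomain)) {
    eps <- 1 / 255
    lp <- log(px + eps)
    if (is.na(vn)) vn <- estimateNoiseVariance(GrayImage(clamp01(
      (lp - min(lp)) / max(1e-12, diff(range(lp))))))  # scale-matched estimate
    st <- localStats(lp, w)
    gain <- ifelse(st$var > vn, (st$var - vn) / pmax(st$var, 1e-300), 0)
    out <- exp(st$mean + gain * (lp - st$mean)) - eps
  } else {
    if (is.na(vn)) vn <- estimateNoiseVariance(img)
    if (vn == 0) return(img)  # gain is identically 1: identity filter
    st <- localStats(px, w)
    # v > vn implies v > 0, so the division is safe; vn = 0 gives gain 1 exactly
    gain <- ifelse(st$var > vn, (st$var - vn) / pmax(st$var, 1e-300), 0)
    out <- st$mean + gain * (px - st$mean)
  }
  GrayImage(clamp01(out))
}
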