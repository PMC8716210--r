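# Synthetic fovea-centered OCT B-scan phantoms with ground-truth masks.
#
# Construction order: background -> horizontal sublayers -> Gaussian
# foveal pit carved from the top -> optional full-thickness hole ->
# vessel shadows (columnwise attenuation) -> multiplicative gamma speckle
# (mean 1, variance 1/looks, the standard fully-developed-speckle model)
# -> Gaussian detector blur -> clip to [0, 1]. The truth mask is the
# PRE-NOISE hole region, so evaluation measures recovery of the latent
# object, not of a noisy appearance.

#' Construct a PhantomSpec
#'
#' Defaults mimic a standardized fovea-centered scan: 224 x 224 px with
#' the retinal band in rows 60-150, a 25 px deep Gaussian pit (sigma
#' 30 px) at the center column, a 30-column full-thickness hole, speckle
#' with 8 looks and 1 px detector blur.
#'
#' @param height,width image size (default 224 x 224).
#' @param bandTop,bandBottom retinal band rows (default 60, 150).
#' @param layerLevels sublayer reflectivities top-to-bottom, each in
#'   (0, 1\] (default `c(0.55, 0.40, 0.65, 0.85)`: bright inner surface,
#'   dimmer nuclear layers, bright outer retina and RPE).
#' @param pitDepth,pitSigma foveal pit depth and Gaussian width in px.
#' @param hasHole whether to carve a full-thickness hole.
#' @param holeWidth hole width in columns (default 30).
#' @param holeCol pit/hole center column (default: image center).
#' @param speckleLooks speckle looks (variance 1/looks); `Inf` disables.
#' @param shadowCols list of `c(col, width, attenuation)` triples.
#' @param blurSigma Gaussian blur sigma in px (default 1).
#' @param seed RNG seed.
#' @return A [PhantomSpec-class].
#' @export
PhantomSpec <- function(height = 224L, width = 224L,
                        bandTop = 60L, bandBottom = 150L,
                        layerLevels = c(0.55, 0.40, 0.65, 0.85),
                        pitDepth = 25L, pitSigma = 30,
                        hasHole = TRUE, holeWidth = 30L, holeCol = NULL,
                        speckleLooks = 8, shadowCols = list(),
                        blurSigma = 1, seed = 1L) {
  if (is.null(holeCol)) holeCol <- as.integer(round(width / 2))
  new("PhantomSpec", height = as.integer(height), width = as.integer(width),
      bandTop = as.integer(bandTop), bandBottom = as.integer(bandBottom),
      layerLevels = as.numeric(layerLevels), pitDepth = as.integer(pitDepth),
      pitSigma = as.numeric(pitSigma), hasHole = isTRUE(hasHole),
      holeWidth = as.integer(holeWidth), holeCol = as.integer(holeCol),
      speckleLooks = as.numeric(speckleLooks), shadowCols = shadowCols,
      blurSigma = as.numeric(blurSigma), seed = as.integer(seed))
}

.phantomBackground <- 0.05

# Noise-free phantom scene and truth mask (deterministic, no RNG).
.phantomScene <- function(spec) {
  h <- spec@height; w <- spec@width
  img <- matrix(.phantomBackground, h, w)
  nl <- length(spec@layerLevels)
  bandRows <- spec@bandTop:spec@bandBottom
  cutpts <- round(seq(0, length(bandRows), length.out = nl + 1L))
  for (i in seq_len(nl)) {
    rr <- bandRows[(cutpts[i] + 1L):cutpts[i + 1L]]
    img[rr, ] <- spec@layerLevels[i]
  }
  cols <- seq_len(w)
  pit <- as.integer(round(spec@pitDepth *
                          exp(-(cols - spec@holeCol)^2 / (2 * spec@pitSigma^2))))
  pit <- pmin(pit, spec@bandBottom - spec@bandTop)  # never punch through
  for (c in cols) {
    if (pit[c] >= 1L)
      img[spec@bandTop:(spec@bandTop + pit[c] - 1L), c] <- .phantomBackground
  }
  truth <- matrix(0, h, w)
  if (spec@hasHole) {
    start <- spec@holeCol - (spec@holeWidth - 1L) %/% 2L
    hc <- start:(start + spec@holeWidth - 1L)
    hc <- hc[hc >= 1L & hc <= w]
    for (c in hc) {
      rr <- (spec@bandTop + pit[c]):spec@bandBottom
      img[rr, c] <- .phantomBackground
      truth[rr, c] <- 1
    }
  }
  list(img = img, truth = truth, pit = pit)
}

#' Generate a synthetic B-scan phantom
#'
#' Deterministic under a fixed seed: the same spec always produces the
#' bit-identical image and mask.
#'
#' @param spec a [PhantomSpec-class].
#' @return List with `image` ([GrayImage-class]), `truth`
#'   ([BinaryMask-class], empty when `hasHole` is `FALSE`) and `spec`.
#' @examples
#' ph <- generatePhantom(PhantomSpec(holeWidth = 40L, seed = 3))
#' sum(pixels(ph$truth))
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  sc <- .phantomScene(spec)
  img <- sc$img
  for (s in spec@shadowCols) {
    cc <- s[1]:min(spec@width, s[1] + s[2] - 1)
    img[, cc] <- img[, cc] * s[3]
  }
  img <- withLocalSeed(spec@seed, {
    if (is.finite(spec@speckleLooks)) {
      looks <- spec@speckleLooks
      img <- img * matrix(stats::rgamma(length(img), shape = looks, rate = looks),
                          nrow(img), ncol(img))
    }
    img
  })
  if (spec@blurSigma > 0) img <- gaussianBlur(img, spec@blurSigma)
  list(image = GrayImage(clamp01(img)), truth = BinaryMask(sc$truth),
       spec = spec)
}

#' Generate a seeded phantom dataset
#'
#' Draws `n` per-image specifications from parameter ranges under a master
#' seed (per-image seeds are derived deterministically from it) and
#' generates the phantoms. Ranges default to a plausible clinical spread:
#' 70% of scans carry a hole of width 20-50 px, pit depth 15-30 px,
#' speckle 4-16 looks, 30% with a vessel shadow.
#'
#' @param n number of phantoms (>= 1).
#' @param ranges named list overriding any of `holeProb`, `holeWidth`,
#'   `pitDepth`, `speckleLooks`, `shadowProb`, `shadowWidth`,
#'   `shadowAtten`, `holeColJitter` (two-element min/max ranges except the
#'   probabilities).
#' @param seed master seed.
#' @return List with `phantoms` (list of [generatePhantom()] triples) and
#'   `manifest` (data.frame of the drawn specs).
#' @export
generateDataset <- function(n, ranges = list(), seed = 1L) {
  if (n < 1L) mhStop("validation_error", "n must be >= 1")
  def <- list(holeProb = 0.7, holeWidth = c(20L, 50L), pitDepth = c(15L, 30L),
              speckleLooks = c(4L, 16L), shadowProb = 0.3,
              shadowWidth = c(3L, 8L), shadowAtten = c(0.5, 0.8),
              holeColJitter = c(-10L, 10L))
  for (nm in names(ranges)) {
    if (length(ranges[[nm]]) == 0L)
      mhStop("validation_error", sprintf("empty range for '%s'", nm))
    def[[nm]] <- ranges[[nm]]
  }
  draws <- withLocalSeed(seed, {
    lapply(seq_len(n), function(i) {
      hole <- stats::runif(1) < def$holeProb
      jit <- sample(def$holeColJitter[1]:def$holeColJitter[2], 1L)
      shadows <- list()
      if (stats::runif(1) < def$shadowProb) {
        shadows <- list(c(sample(30:190, 1L),
                          sample(def$shadowWidth[1]:def$shadowWidth[2], 1L),
                          stats::runif(1, def$shadowAtten[1], def$shadowAtten[2])))
      }
      list(hasHole = hole,
           holeWidth = sample(def$holeWidth[1]:def$holeWidth[2], 1L),
           pitDepth = sample(def$pitDepth[1]:def$pitDepth[2], 1L),
           speckleLooks = sample(def$speckleLooks[1]:def$speckleLooks[2], 1L),
           holeCol = 112L + jit, shadowCols = shadows,
           seed = sample.int(.Machine$integer.max, 1L))
    })
  })
  phantoms <- lapply(draws, function(d) {
    generatePhantom(PhantomSpec(
      hasHole = d$hasHole, holeWidth = d$holeWidth, pitDepth = d$pitDepth,
      speckleLooks = d$speckleLooks, holeCol = d$holeCol,
      shadowCols = d$shadowCols, seed = d$seed))
  })
  manifest <- do.call(rbind, lapply(seq_along(draws), function(i) {
    d <- draws[[i]]
    data.frame(id = i, hasHole = d$hasHole, holeWidth = d$holeWidth,
               pitDepth = d$pitDepth, speckleLooks = d$speckleLooks,
               holeCol = d$holeCol, nShadows = length(d$shadowCols),
               seed = d$seed)
  }))
  list(phantoms = phantoms, manifest = manifest)
}
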