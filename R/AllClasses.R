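#' @import methods
NULL

# ---- GrayImage ---------------------------------------------------------

#' Grayscale OCT B-scan image
#'
#' The working representation of a single B-scan: a real-valued intensity
#' matrix normalized to \[0, 1\]. Row 1 is the top of the scan (vitreous
#' side); column index grows laterally. All indices in this package are
#' 1-based and ranges inclusive.
#'
#' @slot pixels numeric matrix of intensities in \[0, 1\].
#' @export
setClass("GrayImage", representation(pixels = "matrix"), validity = function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be numeric")
  if (nrow(p) < 3L || ncol(p) < 3L) return("image must be at least 3 x 3")
  if (any(!is.finite(p))) return("all intensities must be finite")
  if (min(p) < 0 || max(p) > 1) return("intensities must lie in [0, 1]")
  TRUE
})

#' Construct a GrayImage from an intensity matrix
#'
#' @param pixels numeric matrix with values in \[0, 1\], at least 3 x 3.
#' @return A [GrayImage-class] object.
#' @examples
#' img <- GrayImage(matrix(runif(25), 5, 5))
#' dim(pixels(img))
#' @export
GrayImage <- function(pixels) {
  storage.mode(pixels) <- "double"
  new("GrayImage", pixels = pixels)
}

# ---- BinaryMask --------------------------------------------------------

#' Binary segmentation mask
#'
#' Carrier for segmentation output and ground truth: a \{0, 1\} matrix with
#' the same geometry conventions as [GrayImage-class].
#'
#' @slot pixels numeric matrix with values exactly 0 or 1.
#' @export
setClass("BinaryMask", representation(pixels = "matrix"), validity = function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be numeric")
  if (!all(p %in% c(0, 1))) return("mask values must be exactly 0 or 1")
  TRUE
})

#' Construct a BinaryMask
#'
#' @param pixels matrix of 0/1 (logical matrices are coerced).
#' @return A [BinaryMask-class] object.
#' @export
BinaryMask <- function(pixels) {
  if (is.logical(pixels)) {
    pixels <- matrix(as.numeric(pixels), nrow(pixels), ncol(pixels))
  }
  storage.mode(pixels) <- "double"
  new("BinaryMask", pixels = pixels)
}

# ---- GradientField -----------------------------------------------------

#' Sobel gradient field
#'
#' Per-pixel horizontal/vertical Sobel responses Lx, Ly together with the
#' gradient magnitude |grad L| = sqrt(Lx^2 + Ly^2) and direction
#' theta = atan2(Ly, Lx) in (-pi, pi].
#'
#' @slot lx,ly numeric matrices, horizontal/vertical derivative responses.
#' @slot magnitude numeric matrix, non-negative.
#' @slot direction numeric matrix of angles in (-pi, pi].
#' @export
setClass("GradientField",
  representation(lx = "matrix", ly = "matrix",
                 magnitude = "matrix", direction = "matrix"),
  validity = function(object) {
    d <- dim(object@lx)
    if (!identical(d, dim(object@ly)) || !identical(d, dim(object@magnitude)) ||
        !identical(d, dim(object@direction)))
      return("all four arrays must share the image shape")
    if (any(object@magnitude < 0)) return("magnitude must be non-negative")
    err <- max(abs(object@magnitude^2 - (object@lx^2 + object@ly^2)))
    if (err > 1e-8) return("magnitude^2 must equal lx^2 + ly^2")
    TRUE
  })

# ---- EdgeProfileModel --------------------------------------------------

#' Blurred-step (erf) edge profile model
#'
#' Models a 1-D intensity transition as
#' f(x) = (Ir - Il)/2 * erf((x - x0) / (sigma * sqrt(2))) + (Ir + Il)/2,
#' i.e. an ideal step of height Ir - Il blurred by a Gaussian of scale
#' sigma. The edge outset and end are taken at x0 -/+ 2*sigma, covering
#' ~95% of the transition.
#'
#' @slot iLeft,iRight asymptotic intensities left/right of the edge, in \[0,1\].
#' @slot sigma edge blur scale in pixels, > 0.
#' @slot center sub-pixel edge position x0 (1-based pixel coordinates).
#' @slot residual residual norm of the fit that produced the model
#'   (NA for hand-constructed models).
#' @export
setClass("EdgeProfileModel",
  representation(iLeft = "numeric", iRight = "numeric",
                 sigma = "numeric", center = "numeric", residual = "numeric"),
  validity = function(object) {
    if (object@sigma <= 0) return("sigma must be > 0")
    if (object@iLeft < 0 || object@iLeft > 1 ||
        object@iRight < 0 || object@iRight > 1)
      return("iLeft and iRight must lie in [0, 1]")
    TRUE
  })

#' Construct an EdgeProfileModel
#'
#' @param iLeft,iRight asymptotic intensities in \[0, 1\].
#' @param sigma blur scale in pixels (> 0).
#' @param center edge position in pixels.
#' @param residual optional residual norm (NA by default).
#' @return An [EdgeProfileModel-class] object.
#' @export
EdgeProfileModel <- function(iLeft, iRight, sigma, center, residual = NA_real_) {
  new("EdgeProfileModel", iLeft = iLeft, iRight = iRight, sigma = sigma,
      center = center, residual = residual)
}

# ---- IntensityHistogram ------------------------------------------------

#' Gray-level histogram on [0, 1]
#'
#' @slot counts integer bin counts.
#' @slot binEdges numeric vector of length `length(counts) + 1`, uniform
#'   partition of \[0, 1\]; bins are right-open except the last.
#' @slot total total pixel count (`sum(counts)`).
#' @export
setClass("IntensityHistogram",
  representation(counts = "integer", binEdges = "numeric", total = "integer"),
  validity = function(object) {
    if (length(object@binEdges) != length(object@counts) + 1L)
      return("binEdges must have length(counts) + 1 entries")
    if (any(object@counts < 0L)) return("counts must be non-negative")
    if (sum(object@counts) != object@total) return("counts must sum to total")
    e <- object@binEdges
    if (abs(e[1L]) > 1e-12 || abs(e[length(e)] - 1) > 1e-12 || any(diff(e) <= 0))
      return("binEdges must increase strictly from 0 to 1")
    TRUE
  })

# ---- ThresholdSet ------------------------------------------------------

#' Ordered multilevel threshold cut points
#'
#' @slot levels strictly increasing gray-level cut points in (0, 1).
#' @slot method `"otsu"` or `"valley"`.
#' @export
setClass("ThresholdSet",
  representation(levels = "numeric", method = "character"),
  validity = function(object) {
    l <- object@levels
    if (length(l) < 1L) return("at least one threshold level required")
    if (any(l <= 0) || any(l >= 1)) return("levels must lie in (0, 1)")
    if (any(diff(l) <= 0)) return("levels must be strictly increasing")
    if (!object@method %in% c("otsu", "valley"))
      return("method must be 'otsu' or 'valley'")
    TRUE
  })

#' Construct a ThresholdSet
#'
#' @param levels strictly increasing cut points in (0, 1).
#' @param method `"otsu"` (default) or `"valley"`.
#' @return A [ThresholdSet-class] object.
#' @export
ThresholdSet <- function(levels, method = "otsu") {
  new("ThresholdSet", levels = as.numeric(levels), method = method)
}

# ---- ClassMap ----------------------------------------------------------

#' Per-pixel gray-level class labels
#'
#' Label of a pixel = number of threshold levels less than or equal to its
#' intensity, so labels range over \{0, ..., k\} and are monotone in
#' intensity. Label 0 is the darkest (background/vitreous/hole) class.
#'
#' @slot labels integer matrix of labels in \{0, ..., k\}.
#' @slot k number of threshold levels.
#' @export
setClass("ClassMap",
  representation(labels = "matrix", k = "integer"),
  validity = function(object) {
    l <- object@labels
    if (min(l) < 0L || max(l) > object@k)
      return("labels must lie in {0, ..., k}")
    TRUE
  })

# ---- RetinaBand --------------------------------------------------------

#' Per-column retinal band boundaries
#'
#' The search-space restriction for hole extraction: for every image column
#' the row of the inner retinal surface (`top`) and the outer retinal
#' boundary (`bottom`), plus a validity flag.
#'
#' @slot top,bottom numeric vectors (length = image width) of row indices.
#' @slot valid logical vector; where TRUE, `top < bottom` holds.
#' @export
setClass("RetinaBand",
  representation(top = "numeric", bottom = "numeric", valid = "logical"),
  validity = function(object) {
    n <- length(object@top)
    if (length(object@bottom) != n || length(object@valid) != n)
      return("top, bottom and valid must have equal length")
    v <- object@valid
    if (any(v) && any(object@top[v] >= object@bottom[v]))
      return("top must be < bottom wherever valid")
    TRUE
  })

# ---- HoleCandidate -----------------------------------------------------

#' A candidate macular-hole component
#'
#' One 8-connected dark component inside the retinal band, with its area,
#' centroid, edge support and fovea-proximity score.
#'
#' @slot mask [BinaryMask-class] of the component.
#' @slot area pixel count.
#' @slot centroid numeric `(row, col)` of the component centroid.
#' @slot edgeSupport fraction of boundary pixels within 2 px of an edge.
#' @slot score non-negative selection score.
#' @export
setClass("HoleCandidate",
  representation(mask = "BinaryMask", area = "integer",
                 centroid = "numeric", edgeSupport = "numeric",
                 score = "numeric"),
  validity = function(object) {
    if (object@area <= 0L) return("area must be positive")
    if (length(object@centroid) != 2L) return("centroid must be (row, col)")
    if (object@score < 0) return("score must be non-negative")
    TRUE
  })

# ---- HoleSegmentation --------------------------------------------------

#' Final macular-hole segmentation result
#'
#' @slot mask final refined [BinaryMask-class] (all-zero when no hole found).
#' @slot foveaColumn detected foveal-center column.
#' @slot band the [RetinaBand-class] used.
#' @slot chosen the selected [HoleCandidate-class], or NULL.
#' @slot allCandidates list of all surviving candidates.
#' @slot provenance list of parameters and diagnostics (fovea off-center
#'   flag, threshold levels, candidate table).
#' @export
setClass("HoleSegmentation",
  representation(mask = "BinaryMask", foveaColumn = "integer",
                 band = "RetinaBand", chosen = "ANY",
                 allCandidates = "list", provenance = "list"))

# ---- PhantomSpec -------------------------------------------------------

#' Parameterization of a synthetic OCT B-scan phantom
#'
#' Full generative specification of a fovea-centered B-scan: a dark
#' vitreous background, a bright multilayer retinal band, a Gaussian foveal
#' pit, an optional full-thickness hole, vessel-shadow artifacts,
#' multiplicative gamma speckle and detector blur.
#'
#' @slot height,width image size in pixels.
#' @slot bandTop,bandBottom first/last rows of the retinal band.
#' @slot layerLevels reflectivity of the band sublayers, each in (0, 1\].
#' @slot pitDepth foveal pit depth in pixels.
#' @slot pitSigma Gaussian pit width in pixels.
#' @slot hasHole whether a full-thickness hole is present.
#' @slot holeWidth hole width in columns.
#' @slot holeCol hole/pit center column.
#' @slot speckleLooks speckle looks (variance 1/looks); `Inf` disables speckle.
#' @slot shadowCols list of `c(col, width, attenuation)` shadow triples.
#' @slot blurSigma Gaussian blur scale in pixels (0 disables).
#' @slot seed RNG seed for the speckle draw.
#' @export
setClass("PhantomSpec",
  representation(height = "integer", width = "integer",
                 bandTop = "integer", bandBottom = "integer",
                 layerLevels = "numeric", pitDepth = "integer",
                 pitSigma = "numeric", hasHole = "logical",
                 holeWidth = "integer", holeCol = "integer",
                 speckleLooks = "numeric", shadowCols = "list",
                 blurSigma = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@height < 3L || object@width < 3L) return("phantom must be at least 3 x 3")
    if (object@bandTop < 1L || object@bandTop >= object@bandBottom ||
        object@bandBottom > object@height)
      return("need 1 <= bandTop < bandBottom <= height")
    if (any(object@layerLevels <= 0) || any(object@layerLevels > 1))
      return("layerLevels must lie in (0, 1]")
    if (object@pitDepth < 0L) return("pitDepth must be >= 0")
    if (object@pitSigma <= 0) return("pitSigma must be > 0")
    if (object@holeWidth < 1L || object@holeWidth >= object@width)
      return("holeWidth must be in [1, width)")
    if (object@holeCol < 1L || object@holeCol > object@width)
      return("holeCol must be a valid column")
    if (object@speckleLooks < 1) return("speckleLooks must be >= 1")
    if (object@blurSigma < 0) return("blurSigma must be >= 0")
    for (s in object@shadowCols)
      if (length(s) != 3L || s[1] < 1 || s[2] < 1 || s[3] <= 0 || s[3] > 1)
        return("each shadow must be c(col >= 1, width >= 1, attenuation in (0,1])")
    TRUE
  })
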