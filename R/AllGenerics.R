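# Accessor generics and show methods for the core classes.

#' Extract the pixel matrix
#'
#' @param x a [GrayImage-class] or [BinaryMask-class].
#' @return The underlying numeric matrix.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "GrayImage", function(x) x@pixels)

#' @rdname pixels
#' @export
setMethod("pixels", "BinaryMask", function(x) x@pixels)

#' Threshold cut points of a ThresholdSet
#'
#' @param x a [ThresholdSet-class].
#' @return Numeric vector of strictly increasing levels in (0, 1).
#' @export
setGeneric("thresholdLevels", function(x) standardGeneric("thresholdLevels"))

#' @rdname thresholdLevels
#' @export
setMethod("thresholdLevels", "ThresholdSet", function(x) x@levels)

#' Label matrix of a ClassMap
#'
#' @param x a [ClassMap-class].
#' @return Integer matrix of labels in \{0, ..., k\}.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname classLabels
#' @export
setMethod("classLabels", "ClassMap", function(x) x@labels)

#' Final hole mask of a segmentation result
#'
#' @param x a [HoleSegmentation-class].
#' @return A [BinaryMask-class].
#' @export
setGeneric("holeMask", function(x) standardGeneric("holeMask"))

#' @rdname holeMask
#' @export
setMethod("holeMask", "HoleSegmentation", function(x) x@mask)

#' Detected foveal-center column
#'
#' @param x a [HoleSegmentation-class].
#' @return Integer column index.
#' @export
setGeneric("foveaColumn", function(x) standardGeneric("foveaColumn"))

#' @rdname foveaColumn
#' @export
setMethod("foveaColumn", "HoleSegmentation", function(x) x@foveaColumn)

#' Edge outset and end of a fitted edge profile
#'
#' The outset and end of the transition are taken at
#' `center - 2*sigma` and `center + 2*sigma`, bracketing about 95% of the
#' intensity change of the blurred step.
#'
#' @param x an [EdgeProfileModel-class].
#' @return Named numeric vector `c(outset, end)`.
#' @export
setGeneric("edgeBounds", function(x) standardGeneric("edgeBounds"))

#' @rdname edgeBounds
#' @export
setMethod("edgeBounds", "EdgeProfileModel", function(x)
  c(outset = x@center - 2 * x@sigma, end = x@center + 2 * x@sigma))

#' @describeIn GrayImage-class dimensions of the pixel matrix
#' @param x a GrayImage
#' @export
setMethod("dim", "GrayImage", function(x) dim(x@pixels))

#' @describeIn BinaryMask-class dimensions of the pixel matrix
#' @param x a BinaryMask
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@pixels))

setMethod("show", "GrayImage", function(object) {
  p <- object@pixels
  cat(sprintf("GrayImage %d x %d, intensity range [%.4f, %.4f]\n",
              nrow(p), ncol(p), min(p), max(p)))
})

setMethod("show", "BinaryMask", function(object) {
  p <- object@pixels
  cat(sprintf("BinaryMask %d x %d, %d foreground px (%.2f%%)\n",
              nrow(p), ncol(p), sum(p), 100 * mean(p)))
})

setMethod("show", "GradientField", function(object) {
  cat(sprintf("GradientField %d x %d, max |grad| = %.4f\n",
              nrow(object@lx), ncol(object@lx), max(object@magnitude)))
})

setMethod("show", "EdgeProfileModel", function(object) {
  b <- edgeBounds(object)
  cat(sprintf(paste0("EdgeProfileModel: Il = %.4f, Ir = %.4f, sigma = %.3f px, ",
                     "center = %.3f px\n  outset = %.3f, end = %.3f, residual = %s\n"),
              object@iLeft, object@iRight, object@sigma, object@center,
              b["outset"], b["end"],
              ifelse(is.na(object@residual), "NA", sprintf("%.3g", object@residual))))
})

setMethod("show", "ThresholdSet", function(object) {
  cat(sprintf("ThresholdSet (%s): %s\n", object@method,
              paste(sprintf("%.4f", object@levels), collapse = ", ")))
})

setMethod("show", "ClassMap", function(object) {
  cat(sprintf("ClassMap %d x %d, k = %d thresholds (%d classes)\n",
              nrow(object@labels), ncol(object@labels), object@k, object@k + 1L))
})

setMethod("show", "RetinaBand", function(object) {
  v <- object@valid
  cat(sprintf("RetinaBand over %d columns, %d valid (%.1f%%)\n",
              length(v), sum(v), 100 * mean(v)))
  if (any(v))
    cat(sprintf("  median top = %.1f, median bottom = %.1f\n",
                stats::median(object@top[v]), stats::median(object@bottom[v])))
})

setMethod("show", "HoleCandidate", function(object) {
  cat(sprintf("HoleCandidate: area = %d px, centroid = (%.1f, %.1f), edge support = %.2f, score = %.2f\n",
              object@area, object@centroid[1], object@centroid[2],
              object@edgeSupport, object@score))
})

setMethod("show", "HoleSegmentation", function(object) {
  cat(sprintf("HoleSegmentation: fovea column %d, %d candidate(s), %s\n",
              object@foveaColumn, length(object@allCandidates),
              if (is.null(object@chosen)) "no hole detected"
              else sprintf("hole area %d px", as.integer(sum(object@mask@pixels)))))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec %d x %d: band rows [%d, %d], pit depth %d px, ",
                     "%s, speckle looks %s, blur sigma %.1f, seed %d\n"),
              object@height, object@width, object@bandTop, object@bandBottom,
              object@pitDepth,
              if (object@hasHole) sprintf("hole width %d at col %d",
                                          object@holeWidth, object@holeCol)
              else "no hole",
              format(object@speckleLooks), object@blurSigma, object@seed))
})
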