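# Derivative-based edge information: Sobel gradient fields and the erf
# blurred-step edge-profile model with sub-pixel outset/end localization.
#
# Kernels are applied by correlation (no flip) under replicate padding;
# zero padding would create spurious border edges along the bright retinal
# band. Sign conventions: lx grows with intensity increasing toward larger
# column index; ly grows with intensity increasing toward SMALLER row
# index (upward, toward the vitreous). Magnitude and direction modulo sign
# are unaffected by these conventions.

.sobelKx <- matrix(c(-1, 0, 1,
                     -2, 0, 2,
                     -1, 0, 1), 3, 3, byrow = TRUE)
.sobelKy <- matrix(c( 1,  2,  1,
                      0,  0,  0,
                     -1, -2, -1), 3, 3, byrow = TRUE)

#' Sobel gradient field of a B-scan
#'
#' Correlates the image with the 3x3 Sobel kernel pair under replicate
#' padding and derives the gradient magnitude `sqrt(lx^2 + ly^2)` and
#' direction `atan2(ly, lx)` (mapped to (-pi, pi\]).
#'
#' @param img a [GrayImage-class] (at least 3 x 3).
#' @return A [GradientField-class].
#' @examples
#' ramp <- GrayImage(matrix(rep(seq(0, 1, length.out = 8), each = 8), 8, 8))
#' gf <- sobelGradients(ramp)
#' @export
sobelGradients <- function(img) {
  stopifnot(is(img, "GrayImage"))
  px <- img@pixels
  if (nrow(px) < 3L || ncol(px) < 3L)
    mhStop("validation_error", "image must be at least 3 x 3 for Sobel kernels")
  # separable difference form (smooth across, difference along): exact
  # zeros on constant images, unlike a sequential kernel accumulation
  p <- padReplicate(px, 1L, 1L)
  ri <- seq_len(nrow(px)) + 1L; ci <- seq_len(ncol(px)) + 1L
  sh <- function(dr, dc) p[ri + dr, ci + dc]
  right <- sh(-1L, 1L) + 2 * sh(0L, 1L) + sh(1L, 1L)
  left  <- sh(-1L, -1L) + 2 * sh(0L, -1L) + sh(1L, -1L)
  up    <- sh(-1L, -1L) + 2 * sh(-1L, 0L) + sh(-1L, 1L)
  down  <- sh(1L, -1L) + 2 * sh(1L, 0L) + sh(1L, 1L)
  lx <- right - left
  ly <- up - down
  mag <- sqrt(lx^2 + ly^2)
  dir <- atan2(ly, lx)
  dir[dir <= -pi] <- pi
  new("GradientField", lx = lx, ly = ly, magnitude = mag, direction = dir)
}

#' Evaluate the erf edge-profile model
#'
#' The blurred-step model
#' `f(x) = (Ir - Il)/2 * erf((x - x0)/(sigma*sqrt(2))) + (Ir + Il)/2`,
#' equivalently `Il + (Ir - Il) * pnorm((x - x0)/sigma)`: the profile of an
#' ideal intensity step blurred by a Gaussian point-spread of scale sigma.
#'
#' @param model an [EdgeProfileModel-class].
#' @param x numeric vector of positions (pixels).
#' @return Numeric vector `f(x)`.
#' @export
edgeProfileValue <- function(model, x) {
  stopifnot(is(model, "EdgeProfileModel"))
  model@iLeft + (model@iRight - model@iLeft) *
    stats::pnorm((x - model@center) / model@sigma)
}

#' Fit the erf edge-profile model to a 1-D scanline
#'
#' Least-squares fit of the blurred-step model, giving sub-pixel edge
#' localization. Positions are 1-based pixel indices along the scanline.
#' Initialization: `iLeft`/`iRight` from the first/last-quartile means,
#' `center` at the maximum absolute finite difference, `sigma = 1`;
#' bounded Levenberg-Marquardt optimization with
#' `sigma` in \[0.3, length/2\]. The edge outset and end (`center -/+
#' 2*sigma`) are available via [edgeBounds()].
#'
#' @param scanline numeric vector, length >= 7, not constant.
#' @return An [EdgeProfileModel-class] with the residual norm in its
#'   `residual` slot.
#' @export
fitEdgeProfile <- function(scanline) {
  n <- length(scanline)
  if (n < 7L) mhStop("validation_error", "scanline must have at least 7 samples")
  if (stats::sd(scanline) < 1e-12)
    mhStop("no_edge", "constant scanline: no edge to fit")
  x <- seq_len(n)
  q <- max(2L, n %/% 4L)
  iL0 <- mean(scanline[seq_len(q)])
  iR0 <- mean(scanline[n - seq_len(q) + 1L])
  c0 <- which.max(abs(diff(scanline))) + 0.5
  start <- c(iL = iL0, iR = iR0, sigma = 1, center = c0)
  lower <- c(0, 0, 0.3, 1)
  upper <- c(1, 1, n / 2, n)
  resid <- function(p) {
    scanline - (p[1] + (p[2] - p[1]) * stats::pnorm((x - p[4]) / p[3]))
  }
  fit <- minpack.lm::nls.lm(
    par = pmin(pmax(start, lower), upper), lower = lower, upper = upper,
    fn = resid,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  if (fit$info %in% c(0L, 5L))
    mhStop("fit_failure",
           sprintf("edge-profile fit did not converge (info %d: %s)",
                   fit$info, fit$message))
  p <- fit$par
  EdgeProfileModel(iLeft = unname(p[1]), iRight = unname(p[2]),
                   sigma = unname(p[3]), center = unname(p[4]),
                   residual = sqrt(fit$deviance))
}

#' Binarize a gradient field at a relative magnitude threshold
#'
#' Marks pixels whose gradient magnitude is at least
#' `relThreshold * max(magnitude)`. An all-zero magnitude field yields an
#' empty mask for any threshold.
#'
#' @param field a [GradientField-class].
#' @param relThreshold relative threshold in \[0, 1\] (default 0.2).
#' @return A [BinaryMask-class].
#' @export
edgeMap <- function(field, relThreshold = 0.2) {
  stopifnot(is(field, "GradientField"))
  if (relThreshold < 0 || relThreshold > 1)
    mhStop("validation_error", "relThreshold must lie in [0, 1]")
  mx <- max(field@magnitude)
  if (mx == 0) return(BinaryMask(matrix(0, nrow(field@magnitude), ncol(field@magnitude))))
  BinaryMask(field@magnitude >= relThreshold * mx)
}
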