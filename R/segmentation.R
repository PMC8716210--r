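# Fusing the class map and edge map: retinal band localization, foveal
# depression detection, and extraction of the macular-hole region.
#
# Fusion order: threshold first, edges as evidence. The darkest class
# (label 0) defines hole/vitreous tissue; a hole is distinguished from
# vitreous by containment in the retinal band. Edge information enters as
# a support filter and a score term rather than by edge linking, which is
# fragile on speckled scans.

#' Detect the retinal band from a class map
#'
#' Per column, `top` is the first and `bottom` the last row with a
#' non-background label (label >= 1); both traces are median filtered
#' (7-column window) to remove single-column spikes. Columns with no
#' non-background pixel are invalid; interior invalid runs flanked by
#' valid columns (as produced by a full-thickness hole, which blanks its
#' columns in the class map) are bridged by linear interpolation of the
#' traces and marked valid so that hole pixels stay inside the band.
#'
#' @param classmap a [ClassMap-class].
#' @param medianWindow odd median-filter window in columns (default 7).
#' @return A [RetinaBand-class].
#' @export
detectRetinaBand <- function(classmap, medianWindow = 7L) {
  stopifnot(is(classmap, "ClassMap"))
  lab <- classmap@labels
  w <- ncol(lab)
  fg <- lab >= 1L
  hasFg <- colSums(fg) > 0L
  if (mean(!hasFg) > 0.5)
    mhStop("no_retina", sprintf("only %d of %d columns contain retina",
                                sum(hasFg), w))
  top <- rep(NA_real_, w); bottom <- rep(NA_real_, w)
  for (c in which(hasFg)) {
    rows <- which(fg[, c])
    top[c] <- rows[1L]; bottom[c] <- rows[length(rows)]
  }
  vi <- which(hasFg)
  # median filter along the VALID-column subsequence first: spike columns
  # flanking an interior gap (e.g. blur-eroded hole borders) sit next to
  # their clean neighbors there, so the median removes them before they
  # can anchor the interpolation across the gap
  clean <- function(tr) {
    tv <- tr[vi]
    if (length(tv) >= medianWindow)
      tv <- stats::runmed(tv, medianWindow, endrule = "median")
    if (length(vi) == 1L) return(rep(tv, w))
    stats::approx(vi, tv, xout = seq_len(w), rule = 2)$y
  }
  top <- clean(top); bottom <- clean(bottom)
  # valid = observed columns plus interpolated interior gaps
  valid <- seq_len(w) >= min(vi) & seq_len(w) <= max(vi)
  valid <- valid & top < bottom
  new("RetinaBand", top = as.numeric(top), bottom = as.numeric(bottom),
      valid = valid)
}

#' Locate the foveal center column
#'
#' The foveal pit is the thickness minimum of the retinal band near the
#' scan center: the argmin of the smoothed per-column thickness
#' (`bottom - top`), restricted to the central half of the width. Ties go
#' to the column closest to the center (then leftmost). If the
#' whole-width minimum falls outside the central half the central-half
#' minimum is still returned, flagged via `attr(, "offCenter")`.
#'
#' @param band a [RetinaBand-class].
#' @param smoothWindow moving-average window in columns (default 11).
#' @return Integer column index with attribute `offCenter` (logical).
#' @export
locateFoveaCenter <- function(band, smoothWindow = 11L) {
  stopifnot(is(band, "RetinaBand"))
  w <- length(band@top)
  th <- ifelse(band@valid, band@bottom - band@top, NA_real_)
  ok <- !is.na(th)
  if (any(ok) && sum(ok) > 1L) {
    sm <- th
    sm[ok] <- smoothVec(th[ok], smoothWindow)
    th <- sm
  }
  central <- seq_len(w) >= floor(w / 4) + 1L & seq_len(w) <= ceiling(3 * w / 4)
  cand <- which(central & !is.na(th))
  if (!length(cand))
    mhStop("fovea_not_found", "no valid band columns in the central half")
  mn <- min(th[cand])
  ties <- cand[th[cand] == mn]
  centerCol <- (w + 1) / 2
  fovea <- ties[order(abs(ties - centerCol), ties)][1L]
  globalMin <- min(th, na.rm = TRUE)
  structure(as.integer(fovea), offCenter = globalMin < mn - 1e-9)
}

#' Extract macular-hole candidate components
#'
#' Candidate pixels are darkest-class (label 0) pixels strictly inside the
#' retinal band. 8-connected components are filtered by minimum area and
#' by edge support (fraction of component boundary pixels within 2 px of
#' an edge-map pixel), then scored by
#' `area * edgeSupport * exp(-|centroidCol - foveaCol| / (width * decayFrac))`
#' — a soft prior for the foveal depression rather than a hard crop.
#'
#' @param classmap a [ClassMap-class].
#' @param edges a [BinaryMask-class] edge map (e.g. from [edgeMap()]).
#' @param band a [RetinaBand-class].
#' @param foveaCol fovea center column (from [locateFoveaCenter()]).
#' @param minArea minimum component area in px (default 25).
#' @param minEdgeSupport minimum boundary edge-support fraction (default 0.1).
#' @param decayFrac spatial decay constant as a fraction of width (default 1/8).
#' @return List of [HoleCandidate-class] (possibly empty).
#' @export
extractHoleCandidates <- function(classmap, edges, band, foveaCol,
                                  minArea = 25L, minEdgeSupport = 0.1,
                                  decayFrac = 1 / 8) {
  stopifnot(is(classmap, "ClassMap"), is(edges, "BinaryMask"),
            is(band, "RetinaBand"))
  lab <- classmap@labels
  h <- nrow(lab); w <- ncol(lab)
  if (!identical(dim(edges@pixels), dim(lab)) || length(band@top) != w)
    mhStop("validation_error", "classmap, edges and band shapes differ")
  rows <- matrix(seq_len(h), h, w)
  topM <- matrix(band@top, h, w, byrow = TRUE)
  botM <- matrix(band@bottom, h, w, byrow = TRUE)
  validM <- matrix(band@valid, h, w, byrow = TRUE)
  inside <- validM & rows > topM & rows < botM
  cand <- (lab == 0L) & inside
  if (!any(cand)) return(list())
  comp <- label8(cand)
  dil <- correlate2d(edges@pixels, matrix(1, 5, 5), pad = "zero") > 0
  out <- list()
  for (id in seq_len(max(comp))) {
    m <- comp == id
    area <- sum(m)
    if (area < minArea) next
    nb <- correlate2d(m + 0, matrix(1, 3, 3), pad = "zero")
    boundary <- m & nb < 9
    support <- mean(dil[boundary])
    if (support < minEdgeSupport) next
    idx <- which(m, arr.ind = TRUE)
    centroid <- c(mean(idx[, 1L]), mean(idx[, 2L]))
    score <- area * support * exp(-abs(centroid[2L] - foveaCol) / (w * decayFrac))
    out[[length(out) + 1L]] <- new("HoleCandidate",
      mask = BinaryMask(m), area = as.integer(area), centroid = centroid,
      edgeSupport = support, score = score)
  }
  out
}

#' Select the macular-hole candidate
#'
#' Maximum-score candidate; ties go to the larger area, then the leftmost
#' centroid. An empty candidate list yields `NULL` (no hole).
#'
#' @param candidates list of [HoleCandidate-class].
#' @return A [HoleCandidate-class] or `NULL`.
#' @export
selectHole <- function(candidates) {
  if (!length(candidates)) return(NULL)
  score <- vapply(candidates, function(x) x@score, numeric(1))
  area <- vapply(candidates, function(x) x@area, integer(1))
  ccol <- vapply(candidates, function(x) x@centroid[2L], numeric(1))
  candidates[[order(-score, -area, ccol)[1L]]]
}

#' Morphological refinement of a hole mask
#'
#' Closing with a 3x3 box, hole filling, then opening with the same
#' element: removes pinholes and hairline gaps while leaving solid convex
#' shapes (e.g. rectangles) untouched. Idempotent on the masks the
#' pipeline produces.
#'
#' @param mask a [BinaryMask-class].
#' @return A refined [BinaryMask-class].
#' @export
refineMask <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  px <- mask@pixels
  if (!any(px > 0)) return(mask)
  kern <- EBImage::makeBrush(3, shape = "box")
  out <- EBImage::opening(EBImage::fillHull(EBImage::closing(px, kern)), kern)
  BinaryMask(matrix(as.numeric(out > 0), nrow(px), ncol(px)))
}
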