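# Multilevel gray-level thresholding: histogram-valley selection (the
# "minimum between two peaks" rule) and exhaustive multilevel Otsu
# (between-class variance maximization) as the robust default.
#
# Tie-breaking is lexicographically smallest / leftmost everywhere so that
# results are deterministic. Otsu thresholds are reported as bin-EDGE
# positions, so applying them to quantized data is exact; valley
# thresholds are bin centers (the valley rule names a bin, not an edge).

#' Build an intensity histogram on [0, 1]
#'
#' Uniform bins over \[0, 1\], right-open except the last bin which is
#' closed at 1.
#'
#' @param img a [GrayImage-class].
#' @param bins number of bins (>= 2; pipeline default 256).
#' @return An [IntensityHistogram-class].
#' @export
buildHistogram <- function(img, bins = 256L) {
  stopifnot(is(img, "GrayImage"))
  bins <- as.integer(bins)
  if (bins < 2L) mhStop("validation_error", "bins must be >= 2")
  px <- as.vector(img@pixels)
  idx <- pmin(bins, floor(px * bins) + 1L)
  new("IntensityHistogram",
      counts = tabulate(idx, nbins = bins),
      binEdges = (0:bins) / bins,
      total = length(px))
}

# Local maxima (leftmost sample of each plateau; signal ends eligible) and
# their topographic prominences: prominence = height - max(leftBase,
# rightBase), each base being the minimum between the peak and the nearest
# strictly higher sample on that side (unbounded if the side is empty).
.peaksWithProminence <- function(s) {
  n <- length(s)
  peaks <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1L] == s[i]) j <- j + 1L   # plateau [i, j]
    leftLower <- i == 1L || s[i - 1L] < s[i]
    rightLower <- j == n || s[j + 1L] < s[i]
    if (leftLower && rightLower) peaks <- c(peaks, i)
    i <- j + 1L
  }
  prom <- vapply(peaks, function(p) {
    v <- s[p]
    lb <- -Inf
    if (p > 1L) {
      left <- s[seq_len(p - 1L)]
      higher <- which(left > v)
      lb <- if (length(higher)) min(left[(max(higher) + 1L):(p - 1L)]) else min(left)
    }
    rb <- -Inf
    if (p < n) {
      right <- s[(p + 1L):n]
      higher <- which(right > v)
      rb <- if (length(higher)) min(right[seq_len(min(higher) - 1L)]) else min(right)
    }
    base <- max(lb, rb)
    if (is.infinite(base)) v else v - base
  }, numeric(1))
  list(pos = peaks, prom = prom)
}

#' Histogram-valley multilevel thresholds
#'
#' Implements the classic valley rule: smooth the histogram with a moving
#' average, locate the `k + 1` highest-prominence peaks, and place each
#' threshold at the minimum-count bin strictly between consecutive peaks
#' (ties broken leftmost). Valley selection is brittle on speckled
#' histograms; callers normally fall back to [otsuMultilevel()] on an
#' insufficient-modes error.
#'
#' @param hist an [IntensityHistogram-class].
#' @param k number of thresholds (>= 1).
#' @param smoothWindow moving-average window in bins (default 5).
#' @return A [ThresholdSet-class] with `method = "valley"`; levels are bin
#'   centers.
#' @export
valleyThresholds <- function(hist, k = 1L, smoothWindow = 5L) {
  stopifnot(is(hist, "IntensityHistogram"))
  k <- as.integer(k)
  if (k < 1L) mhStop("validation_error", "k must be >= 1")
  s <- smoothVec(as.numeric(hist@counts), smoothWindow)
  pk <- .peaksWithProminence(s)
  if (length(pk$pos) < k + 1L)
    mhStop("insufficient_modes",
           sprintf("found %d peak(s) after smoothing; need %d",
                   length(pk$pos), k + 1L))
  ord <- order(-pk$prom, pk$pos)          # highest prominence, ties leftmost
  sel <- sort(pk$pos[ord[seq_len(k + 1L)]])
  centers <- (hist@binEdges[-length(hist@binEdges)] + hist@binEdges[-1L]) / 2
  levels <- numeric(k)
  for (i in seq_len(k)) {
    lo <- sel[i] + 1L; hi <- sel[i + 1L] - 1L
    if (lo > hi)
      mhStop("insufficient_modes",
             sprintf("no bin strictly between peaks at bins %d and %d",
                     sel[i], sel[i + 1L]))
    between <- s[lo:hi]
    levels[i] <- centers[lo + which.min(between) - 1L]   # leftmost minimum
  }
  ThresholdSet(levels, method = "valley")
}

# Between-class "goodness" sum(w_c * mu_c^2) pieces from cumulative
# moments; maximizing it is equivalent to maximizing the between-class
# variance. Boundary index t in 0..bins cuts after bin t.
.otsuMoments <- function(hist) {
  p <- hist@counts / hist@total
  centers <- (hist@binEdges[-length(hist@binEdges)] + hist@binEdges[-1L]) / 2
  list(W = c(0, cumsum(p)), S = c(0, cumsum(p * centers)))
}

.classTerm <- function(mom, a, b) {
  dw <- mom$W[b + 1L] - mom$W[a + 1L]
  ds <- mom$S[b + 1L] - mom$S[a + 1L]
  ifelse(dw > 0, ds * ds / dw, 0)
}

#' Exhaustive multilevel Otsu thresholds
#'
#' Returns the increasing tuple of bin-boundary cut points maximizing the
#' between-class variance, searched exhaustively over all tuples for
#' `k` in 1..3 (ties broken by the lexicographically smallest tuple).
#' Threshold values are bin-edge positions, so [applyThresholds()] is
#' exact on quantized data.
#'
#' @param hist an [IntensityHistogram-class] with at least `k + 1`
#'   occupied bins.
#' @param k number of thresholds, 1 to 3 (pipeline default 3: vitreous,
#'   inner retina, outer retina, hyper-reflective RPE band).
#' @return A [ThresholdSet-class] with `method = "otsu"`.
#' @export
otsuMultilevel <- function(hist, k = 3L) {
  stopifnot(is(hist, "IntensityHistogram"))
  k <- as.integer(k)
  if (k < 1L) mhStop("validation_error", "k must be >= 1")
  if (k > 3L) mhStop("validation_error", "k > 3 is not supported (exhaustive search)")
  if (sum(hist@counts > 0L) < k + 1L)
    mhStop("degenerate_histogram",
           sprintf("need at least %d occupied bins for k = %d", k + 1L, k))
  B <- length(hist@counts)
  mom <- .otsuMoments(hist)
  cuts <- seq_len(B - 1L)
  leftT <- .classTerm(mom, 0L, cuts)          # class [0, t)
  rightT <- .classTerm(mom, cuts, B)          # class [t, B)
  if (k == 1L) {
    val <- leftT + rightT
    t1 <- which.max(val)                      # first max = smallest cut
    return(ThresholdSet(hist@binEdges[t1 + 1L], method = "otsu"))
  }
  # mid[a, b] = term of class [a, b) for 1 <= a < b <= B - 1
  mid <- matrix(-Inf, B - 1L, B - 1L)
  for (a in seq_len(B - 2L)) {
    b <- (a + 1L):(B - 1L)
    mid[a, b] <- .classTerm(mom, a, b)
  }
  if (k == 2L) {
    best <- -Inf; bt <- c(NA_integer_, NA_integer_)
    for (t1 in seq_len(B - 2L)) {
      t2 <- (t1 + 1L):(B - 1L)
      val <- leftT[t1] + mid[t1, t2] + rightT[t2]
      i <- which.max(val)
      if (val[i] > best) { best <- val[i]; bt <- c(t1, t2[i]) }
    }
    return(ThresholdSet(hist@binEdges[bt + 1L], method = "otsu"))
  }
  # k = 3: for each t2 precompute the best (and leftmost) t3 > t2
  best3 <- rep(-Inf, B - 1L); arg3 <- rep(NA_integer_, B - 1L)
  for (t2 in 2:(B - 2L)) {
    t3 <- (t2 + 1L):(B - 1L)
    val <- mid[t2, t3] + rightT[t3]
    i <- which.max(val)
    best3[t2] <- val[i]; arg3[t2] <- t3[i]
  }
  best <- -Inf; bt <- c(NA_integer_, NA_integer_, NA_integer_)
  for (t1 in seq_len(B - 3L)) {
    t2 <- (t1 + 1L):(B - 2L)
    val <- leftT[t1] + mid[t1, t2] + best3[t2]
    i <- which.max(val)
    if (val[i] > best) { best <- val[i]; bt <- c(t1, t2[i], arg3[t2[i]]) }
  }
  ThresholdSet(hist@binEdges[bt + 1L], method = "otsu")
}

#' Apply a threshold set to an image
#'
#' Each pixel's label is the number of threshold levels less than or equal
#' to its value (a pixel exactly at a level belongs to the upper class),
#' giving `k + 1` classes with label 0 the darkest. The labeling is
#' monotone in intensity and idempotent under re-application.
#'
#' @param img a [GrayImage-class].
#' @param ts a [ThresholdSet-class].
#' @return A [ClassMap-class].
#' @export
applyThresholds <- function(img, ts) {
  stopifnot(is(img, "GrayImage"), is(ts, "ThresholdSet"))
  lab <- findInterval(as.vector(img@pixels), ts@levels)
  new("ClassMap",
      labels = matrix(as.integer(lab), nrow(img@pixels), ncol(img@pixels)),
      k = length(ts@levels))
}
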