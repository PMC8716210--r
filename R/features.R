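# Hole shape features, unsupervised feature selection and pixel-wise
# evaluation metrics.

#' Compute shape features of a hole mask
#'
#' Clinical-style size descriptors of a single-component mask:
#' * `area` — pixel count;
#' * `baseWidth` — maximum per-row extent (widest extent of the hole base);
#' * `minDiameter` — minimum per-row extent over rows strictly between the
#'   top and bottom mask rows (the narrowest mid-hole extent; for masks of
#'   height <= 2 it falls back to the minimum over all rows);
#' * `height` — row extent;
#' * `aspect` — `baseWidth / height`;
#' * `circularity` — `4*pi*area / perimeter^2`, with the perimeter
#'   estimated as the Freeman chain-code length of the outer boundary
#'   contour (diagonal steps weighted sqrt(2)) plus a half-pixel outer
#'   offset (`+ pi`), floored at 4; advisory only: discretization can push
#'   it slightly above 1 for tiny masks;
#' * `centroidRow`, `centroidCol`.
#'
#' @param mask a non-empty, single-8-connected-component [BinaryMask-class].
#' @return One-row data.frame of features.
#' @export
computeHoleFeatures <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  px <- mask@pixels
  if (!any(px > 0)) mhStop("validation_error", "empty mask has no features")
  comp <- label8(px > 0)
  if (max(comp) > 1L)
    mhStop("validation_error",
           sprintf("mask has %d components; expected one", max(comp)))
  idx <- which(px > 0, arr.ind = TRUE)
  area <- nrow(idx)
  rowRange <- range(idx[, 1L])
  height <- rowRange[2L] - rowRange[1L] + 1L
  extent <- vapply(split(idx[, 2L], idx[, 1L]),
                   function(cc) max(cc) - min(cc) + 1L, numeric(1))
  extRows <- as.integer(names(extent))
  baseWidth <- max(extent)
  interior <- extRows > rowRange[1L] & extRows < rowRange[2L]
  minDiameter <- if (any(interior)) min(extent[interior]) else min(extent)
  oc <- EBImage::ocontour(px)[[1L]]
  steps <- rbind(diff(oc), oc[1L, ] - oc[nrow(oc), ])
  perimeter <- max(sum(sqrt(rowSums(steps^2))) + pi, 4)
  data.frame(
    area = as.integer(area),
    baseWidth = as.integer(baseWidth),
    minDiameter = as.integer(minDiameter),
    height = as.integer(height),
    aspect = baseWidth / height,
    circularity = 4 * pi * area / perimeter^2,
    centroidRow = mean(idx[, 1L]),
    centroidCol = mean(idx[, 2L])
  )
}

#' Unsupervised feature selection by variance and redundancy
#'
#' Drops zero-variance features, ranks the rest by the variance of their
#' min-max-scaled values (a scale-free spread measure), and greedily keeps
#' the highest-ranked features whose absolute Pearson correlation with
#' every already-kept feature is at most `maxCor`. Returns the first `k`
#' survivors (or all, if fewer).
#'
#' @param table data.frame of per-image feature records (numeric columns
#'   are considered), >= 2 rows.
#' @param k number of features to select (>= 1).
#' @param maxCor redundancy cutoff on absolute pairwise correlation
#'   (default 0.95).
#' @return Character vector of selected feature names.
#' @export
selectFeatures <- function(table, k, maxCor = 0.95) {
  table <- as.data.frame(table)
  if (nrow(table) < 2L) mhStop("validation_error", "need at least 2 records")
  if (k < 1L) mhStop("validation_error", "k must be >= 1")
  num <- table[vapply(table, is.numeric, logical(1))]
  sds <- vapply(num, stats::sd, numeric(1))
  num <- num[, sds > 1e-12, drop = FALSE]
  if (ncol(num) == 0L)
    mhStop("no_informative_features", "all features have zero variance")
  scaled <- vapply(num, function(x) (x - min(x)) / (max(x) - min(x)),
                   numeric(nrow(num)))
  spread <- apply(scaled, 2L, stats::var)
  ord <- names(num)[order(-spread, seq_along(spread))]
  kept <- character(0)
  for (nm in ord) {
    if (length(kept) &&
        any(abs(stats::cor(num[[nm]], num[kept])) > maxCor)) next
    kept <- c(kept, nm)
  }
  kept[seq_len(min(k, length(kept)))]
}

#' Pixel-wise confusion counts between two masks
#'
#' @param pred,truth [BinaryMask-class] objects of identical shape.
#' @return Named list with `tp`, `fp`, `fn`, `tn` and `n` (pixel count).
#' @export
confusionCounts <- function(pred, truth) {
  stopifnot(is(pred, "BinaryMask"), is(truth, "BinaryMask"))
  p <- pred@pixels; t <- truth@pixels
  if (!identical(dim(p), dim(t)))
    mhStop("validation_error", "pred and truth shapes differ")
  tp <- sum(p == 1 & t == 1)
  fp <- sum(p == 1 & t == 0)
  fn <- sum(p == 0 & t == 1)
  list(tp = tp, fp = fp, fn = fn, tn = length(p) - tp - fp - fn,
       n = length(p))
}

#' Segmentation metrics from confusion counts
#'
#' Pixel-wise accuracy `(tp+tn)/n`, sensitivity `tp/(tp+fn)`, Jaccard
#' index `tp/(tp+fp+fn)` and Dice coefficient `2*tp/(2*tp+fp+fn)`; the
#' identity `dsc = 2*jaccard/(1+jaccard)` holds wherever Jaccard is
#' defined. When the truth has no positive pixels, sensitivity is
#' undefined and reported as `NA` (never 0), so means over mixed image
#' sets exclude it; likewise Jaccard/Dice are `NA` when both masks are
#' empty.
#'
#' @param counts list from [confusionCounts()].
#' @return One-row data.frame with `tp`, `fp`, `fn`, `tn`, `accuracy`,
#'   `sensitivity`, `jaccard`, `dsc`.
#' @export
metricsFromCounts <- function(counts) {
  if (counts$n == 0L) mhStop("validation_error", "empty masks (n = 0)")
  with(counts, data.frame(
    tp = tp, fp = fp, fn = fn, tn = tn,
    accuracy = (tp + tn) / n,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    jaccard = if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_,
    dsc = if (tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  ))
}

#' Evaluate a predicted mask against ground truth
#'
#' Convenience wrapper: [confusionCounts()] then [metricsFromCounts()].
#'
#' @inheritParams confusionCounts
#' @return One-row data.frame of counts and metrics.
#' @export
evaluateMasks <- function(pred, truth) {
  metricsFromCounts(confusionCounts(pred, truth))
}
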