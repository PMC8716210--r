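mkClassMap <- function(lab, k = 3L) {
  new("ClassMap", labels = matrix(as.integer(lab), nrow(lab), ncol(lab)),
      k = as.integer(k))
}

test_that("the retina band is recovered from a phantom class map", {
  ph <- generatePhantom(PhantomSpec(hasHole = FALSE, pitDepth = 0L, seed = 2))
  den <- adaptiveDenoise(standardizeImage(ph$image))
  cm <- applyThresholds(den, otsuMultilevel(buildHistogram(den), 3))
  band <- detectRetinaBand(cm)
  v <- band@valid
  expect_gt(mean(v), 0.9)
  expect_true(all(abs(band@top[v] - 60) <= 2))
  expect_true(all(abs(band@bottom[v] - 150) <= 2))
})

test_that("all-background class maps raise a no-retina error", {
  lab <- matrix(0L, 50, 50)
  expect_error(detectRetinaBand(mkClassMap(lab)), class = "mhseg_no_retina")
})

test_that("a one-column spike in the band trace is removed by the median filter", {
  lab <- matrix(0L, 100, 60)
  lab[40:80, ] <- 1L
  lab[10:80, 30] <- 1L    # spike: top jumps to row 10 in one column
  band <- detectRetinaBand(mkClassMap(lab))
  expect_equal(band@top[30], 40)
  expect_true(all(band@top == 40))
  expect_true(all(band@bottom == 80))
})

test_that("interior columns blanked by a hole are bridged and stay in-band", {
  lab <- matrix(0L, 100, 60)
  lab[40:80, ] <- 1L
  lab[, 25:35] <- 0L      # full-thickness gap
  band <- detectRetinaBand(mkClassMap(lab))
  expect_true(all(band@valid))
  expect_true(all(abs(band@top[25:35] - 40) <= 1))
  expect_true(all(abs(band@bottom[25:35] - 80) <= 1))
})

test_that("the fovea is the central-half thickness minimum with center tie rule", {
  ph <- generatePhantom(PhantomSpec(hasHole = FALSE, seed = 3))
  den <- adaptiveDenoise(standardizeImage(ph$image))
  cm <- applyThresholds(den, otsuMultilevel(buildHistogram(den), 3))
  fov <- locateFoveaCenter(detectRetinaBand(cm))
  expect_lte(abs(as.integer(fov) - 112), 3)
  expect_false(attr(fov, "offCenter"))

  # perfectly flat band: tie -> column closest to the center
  flat <- new("RetinaBand", top = rep(40, 224), bottom = rep(80, 224),
              valid = rep(TRUE, 224))
  expect_equal(as.integer(locateFoveaCenter(flat)), 112L)

  # pit outside the central half: falls back to the central minimum, flagged
  w <- 224
  top <- rep(40, w); top[36:44] <- 60   # deep pit at column ~40
  off <- new("RetinaBand", top = top, bottom = rep(80, w),
             valid = rep(TRUE, w))
  fov2 <- locateFoveaCenter(off)
  expect_true(attr(fov2, "offCenter"))
  expect_gte(as.integer(fov2), 57)   # stays within the central half

  none <- new("RetinaBand", top = rep(40, 8), bottom = rep(80, 8),
              valid = c(TRUE, TRUE, rep(FALSE, 6)))
  expect_error(locateFoveaCenter(none), class = "mhseg_fovea_not_found")
})

test_that("hole candidates lie inside the band and overlap the phantom truth", {
  ph <- generatePhantom(PhantomSpec(seed = 4))
  den <- adaptiveDenoise(standardizeImage(ph$image))
  grad <- sobelGradients(den)
  em <- edgeMap(grad, 0.2)
  cm <- applyThresholds(den, otsuMultilevel(buildHistogram(den), 3))
  band <- detectRetinaBand(cm)
  fov <- locateFoveaCenter(band)
  cands <- extractHoleCandidates(cm, em, band, fov)
  expect_gte(length(cands), 1L)

  best <- selectHole(cands)
  j <- evaluateMasks(best@mask, ph$truth)$jaccard
  expect_gt(j, 0.5)

  for (cand in cands) {
    idx <- which(pixels(cand@mask) == 1, arr.ind = TRUE)
    expect_true(all(band@valid[idx[, 2]]))
    expect_true(all(idx[, 1] > band@top[idx[, 2]]))
    expect_true(all(idx[, 1] < band@bottom[idx[, 2]]))
  }

  # no-hole phantom: nothing survives the filters
  ph0 <- generatePhantom(PhantomSpec(hasHole = FALSE, seed = 4))
  den0 <- adaptiveDenoise(standardizeImage(ph0$image))
  cm0 <- applyThresholds(den0, otsuMultilevel(buildHistogram(den0), 3))
  band0 <- detectRetinaBand(cm0)
  cands0 <- extractHoleCandidates(cm0, edgeMap(sobelGradients(den0), 0.2),
                                  band0, locateFoveaCenter(band0))
  expect_length(cands0, 0L)
})

test_that("candidate selection prefers score, then area, then leftmost centroid", {
  mk <- function(area, ccol, score) {
    m <- matrix(0, 50, 100); m[10:11, ccol:(ccol + 1)] <- 1
    new("HoleCandidate", mask = BinaryMask(m), area = as.integer(area),
        centroid = c(10, ccol), edgeSupport = 0.5, score = score)
  }
  expect_null(selectHole(list()))
  single <- mk(10, 20, 1)
  expect_identical(selectHole(list(single)), single)

  # equal areas: the fovea-proximal (higher-score) candidate wins
  near <- mk(100, 50, 5); far <- mk(100, 90, 1)
  expect_identical(selectHole(list(far, near)), near)

  # equal scores: larger area, then leftmost
  a <- mk(100, 50, 2); b <- mk(200, 60, 2); c <- mk(200, 40, 2)
  expect_identical(selectHole(list(a, b, c)), c)
})

test_that("the fovea-distance decay dominates candidate scoring", {
  # two same-size dark components inside a synthetic band, one at the
  # fovea column and one 80 columns away: the foveal one must score higher
  lab <- matrix(0L, 100, 224); lab[40:80, ] <- 1L
  lab[55:64, 108:117] <- 0L    # at fovea (col ~112)
  lab[55:64, 28:37] <- 0L      # 80 columns off
  cm <- mkClassMap(lab)
  band <- new("RetinaBand", top = rep(40, 224), bottom = rep(80, 224),
              valid = rep(TRUE, 224))
  edges <- BinaryMask(matrix(1, 100, 224))   # full edge support for both
  cands <- extractHoleCandidates(cm, edges, band, foveaCol = 112)
  expect_length(cands, 2L)
  chosen <- selectHole(cands)
  expect_equal(chosen@centroid[2], 112.5)
})

test_that("mask refinement fills pinholes, keeps rectangles, and is idempotent", {
  empty <- BinaryMask(matrix(0, 20, 20))
  expect_equal(pixels(refineMask(empty)), pixels(empty))

  rect <- matrix(0, 30, 30); rect[10:20, 8:22] <- 1
  expect_equal(pixels(refineMask(BinaryMask(rect))), rect)

  pin <- rect; pin[15, 15] <- 0
  expect_equal(pixels(refineMask(BinaryMask(pin))), rect)

  set.seed(12)
  blob <- matrix(0, 40, 40)
  blob[15:30, 10:30] <- rbinom(16 * 21, 1, 0.85)
  once <- refineMask(BinaryMask(blob))
  twice <- refineMask(once)
  expect_identical(pixels(twice), pixels(once))
})

test_that("the pipeline is deterministic end to end", {
  ph <- generatePhantom(PhantomSpec(seed = 5))
  s1 <- segmentHole(ph$image)
  s2 <- segmentHole(ph$image)
  expect_identical(pixels(holeMask(s1)), pixels(holeMask(s2)))
  expect_identical(foveaColumn(s1), foveaColumn(s2))
  expect_identical(s1@provenance$thresholdLevels, s2@provenance$thresholdLevels)
  expect_identical(s1@provenance$candidates, s2@provenance$candidates)
})
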