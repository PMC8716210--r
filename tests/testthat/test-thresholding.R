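test_that("histograms partition [0, 1] into right-open uniform bins", {
  img <- GrayImage(matrix(0.5, 10, 10))
  h <- buildHistogram(img, 256)
  expect_equal(sum(h@counts > 0), 1L)
  expect_equal(max(h@counts), 100L)
  expect_equal(which(h@counts > 0), 129L)   # 0.5 lands in the upper bin

  set.seed(2)
  any_img <- GrayImage(matrix(runif(300), 15, 20))
  expect_equal(sum(buildHistogram(any_img, 64)@counts), 300L)

  half <- GrayImage(matrix(rep(c(0, 1), each = 50), 10, 10))
  hh <- buildHistogram(half, 256)
  expect_equal(hh@counts[1], 50L)
  expect_equal(hh@counts[256], 50L)

  expect_error(buildHistogram(img, 1), class = "mhseg_validation_error")
})

test_that("valley thresholds sit at the smoothed-histogram minimum between peaks", {
  counts <- rep(0L, 256)
  counts[50] <- 100L; counts[200] <- 100L
  h <- new("IntensityHistogram", counts = counts, binEdges = (0:256) / 256,
           total = 200L)
  ts <- valleyThresholds(h, k = 1, smoothWindow = 5)

  # independent check: exhaustively scan the smoothed histogram
  sm <- as.numeric(stats::filter(c(rep(0, 2), counts, rep(0, 2)),
                                 rep(1 / 5, 5), sides = 2))[3:258]
  peaks <- c(48L, 198L)   # leftmost samples of the smeared plateaus
  between <- (peaks[1] + 1L):(peaks[2] - 1L)
  valley <- between[which.min(sm[between])]
  expect_equal(valley, 53L)
  expect_equal(thresholdLevels(ts), (valley - 0.5) / 256, tolerance = 1e-12)

  unimodal <- new("IntensityHistogram",
                  counts = c(rep(0L, 100), 50L, rep(0L, 155)),
                  binEdges = (0:256) / 256, total = 50L)
  expect_error(valleyThresholds(unimodal, 1), class = "mhseg_insufficient_modes")
})

test_that("symmetric trimodal histograms give mirror-symmetric valley thresholds", {
  # 255 bins so that bin i mirrors to bin 256 - i exactly; smooth bumps so
  # the valley minima are unique (no tie-breaking asymmetry)
  # broad overlapping bumps (sigma 30 bins) at high amplitude so the
  # inter-peak minima are unique samples, not tie-broken plateaus
  i <- 1:255
  counts <- as.integer(round(10000 * exp(-(i - 48)^2 / 1800)) +
                       round(10000 * exp(-(i - 128)^2 / 1800)) +
                       round(10000 * exp(-(i - 208)^2 / 1800)))
  expect_identical(counts, rev(counts))   # construction really is symmetric
  h <- new("IntensityHistogram", counts = counts, binEdges = (0:255) / 255,
           total = sum(counts))
  lv <- thresholdLevels(valleyThresholds(h, k = 2))
  expect_length(lv, 2L)
  expect_equal(lv[1], 1 - lv[2], tolerance = 1e-12)
})

test_that("multilevel Otsu equals the exhaustive brute-force oracle", {
  # crafted delta-mass cases
  mk <- function(counts) new("IntensityHistogram", counts = as.integer(counts),
                             binEdges = (0:length(counts)) / length(counts),
                             total = as.integer(sum(counts)))
  c2 <- rep(0L, 64); c2[floor(0.2 * 64) + 1] <- 50L; c2[floor(0.8 * 64) + 1] <- 50L
  expect_equal(thresholdLevels(otsuMultilevel(mk(c2), 1)), oracleOtsu(c2, 1))
  expect_equal(thresholdLevels(otsuMultilevel(mk(c2), 1)),
               (floor(0.2 * 64) + 1) / 64)   # first boundary above the low mass

  c3 <- rep(0L, 64)
  c3[c(floor(0.1 * 64), floor(0.5 * 64), floor(0.9 * 64)) + 1] <- 30L
  expect_equal(thresholdLevels(otsuMultilevel(mk(c3), 2)), oracleOtsu(c3, 2))

  # random histograms, k = 1..3
  set.seed(55)
  for (i in 1:6) {
    counts <- rpois(64, lambda = sample(c(2, 20), 64, replace = TRUE))
    h <- mk(counts)
    for (k in 1:3) {
      expect_equal(thresholdLevels(otsuMultilevel(h, k)), oracleOtsu(counts, k),
                   tolerance = 1e-12)
    }
  }

  const <- mk(c(100L, rep(0L, 63)))
  expect_error(otsuMultilevel(const, 1), class = "mhseg_degenerate_histogram")
})

test_that("valley and Otsu both cut between the modes of a symmetric bimodal histogram", {
  counts <- rep(0L, 64)
  counts[16] <- 80L; counts[49] <- 80L
  h <- new("IntensityHistogram", counts = counts, binEdges = (0:64) / 64,
           total = 160L)
  modes <- c(15.5, 48.5) / 64   # bin-center positions of the two masses
  for (ts in list(valleyThresholds(h, 1), otsuMultilevel(h, 1))) {
    lv <- thresholdLevels(ts)
    expect_gt(lv, modes[1])
    expect_lt(lv, modes[2])
  }
})

test_that("class labels count thresholds at or below the pixel and are monotone", {
  img <- GrayImage(matrix(c(0.2, 0.8), 4, 4))
  cm <- applyThresholds(img, ThresholdSet(0.5))
  expect_setequal(unique(as.vector(classLabels(cm))), c(0L, 1L))

  boundary <- GrayImage(matrix(0.6, 3, 3))
  cm2 <- applyThresholds(boundary, ThresholdSet(c(0.3, 0.6)))
  expect_true(all(classLabels(cm2) == 2L))   # boundary joins the upper class

  set.seed(77)
  img3 <- GrayImage(matrix(runif(100), 10, 10))
  ts3 <- ThresholdSet(c(0.25, 0.5, 0.75))
  cm3 <- applyThresholds(img3, ts3)
  expect_true(all(classLabels(cm3) %in% 0:3))
  # monotone: raising any pixel never lowers its label
  bumped <- GrayImage(clamp_test(pixels(img3) + 0.1))
  expect_true(all(classLabels(applyThresholds(bumped, ts3)) >= classLabels(cm3)))
  # idempotent under re-application
  expect_identical(classLabels(applyThresholds(img3, ts3)), classLabels(cm3))
})
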