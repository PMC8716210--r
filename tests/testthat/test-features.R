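test_that("shape features of a solid rectangle are exact", {
  m <- matrix(0, 30, 40)
  m[11:20, 11:30] <- 1   # 10 rows x 20 columns
  f <- computeHoleFeatures(BinaryMask(m))
  expect_equal(f$area, 200L)
  expect_equal(f$baseWidth, 20L)
  expect_equal(f$minDiameter, 20L)
  expect_equal(f$height, 10L)
  expect_equal(f$aspect, 2.0)
  expect_equal(f$centroidRow, 15.5)
  expect_equal(f$centroidCol, 20.5)
})

test_that("a discrete disk has near-unit circularity", {
  r <- 15
  g <- expand.grid(row = 1:40, col = 1:40)
  disk <- matrix(as.numeric((g$row - 20)^2 + (g$col - 20)^2 <= r^2), 40, 40)
  f <- computeHoleFeatures(BinaryMask(disk))
  expect_gte(f$circularity, 0.85)
  expect_lte(f$circularity, 1.1)
  expect_equal(f$baseWidth, 2L * r + 1L)
})

test_that("degenerate masks are rejected with validation errors", {
  expect_error(computeHoleFeatures(BinaryMask(matrix(0, 10, 10))),
               class = "mhseg_validation_error")
  two <- matrix(0, 10, 10); two[2, 2] <- 1; two[8, 8] <- 1
  expect_error(computeHoleFeatures(BinaryMask(two)),
               class = "mhseg_validation_error")
})

test_that("feature selection drops constant and redundant columns", {
  set.seed(8)
  tab <- data.frame(
    area = rnorm(20, 100, 30),
    const = rep(5, 20),
    width = rnorm(20, 30, 10)
  )
  tab$width_copy <- tab$width
  sel <- selectFeatures(tab, k = 10)
  expect_false("const" %in% sel)
  expect_equal(sum(c("width", "width_copy") %in% sel), 1L)

  five <- as.data.frame(matrix(rnorm(100), 20, 5,
                               dimnames = list(NULL, paste0("f", 1:5))))
  expect_length(selectFeatures(five, k = 3), 3L)

  allconst <- data.frame(a = rep(1, 5), b = rep(2, 5))
  expect_error(selectFeatures(allconst, k = 1),
               class = "mhseg_no_informative_features")
})

test_that("confusion counts match direct enumeration", {
  p <- matrix(0, 4, 4); t <- matrix(0, 4, 4)
  p[1, 1:4] <- 1; p[2, 1:2] <- 1          # 6 predicted
  t[1, 1:3] <- 1; t[3, 4] <- 1            # 4 true, overlap 3
  cc <- confusionCounts(BinaryMask(p), BinaryMask(t))
  expect_equal(cc[c("tp", "fp", "fn", "tn")],
               list(tp = 3, fp = 3, fn = 1, tn = 9))

  m <- BinaryMask(matrix(c(1, 0), 4, 4))
  ident <- confusionCounts(m, m)
  expect_equal(ident$fp + ident$fn, 0)
  comp <- confusionCounts(m, BinaryMask(1 - pixels(m)))
  expect_equal(comp$tp + comp$tn, 0)

  expect_error(confusionCounts(m, BinaryMask(matrix(0, 3, 3))),
               class = "mhseg_validation_error")
})

test_that("metric formulas and special cases follow their definitions", {
  ev <- metricsFromCounts(list(tp = 50, fp = 10, fn = 10, tn = 30, n = 100))
  expect_equal(ev$accuracy, 0.8)
  expect_equal(ev$sensitivity, 50 / 60)
  expect_equal(ev$jaccard, 50 / 70)
  expect_equal(ev$dsc, 100 / 120)

  perfect <- metricsFromCounts(list(tp = 10, fp = 0, fn = 0, tn = 90, n = 100))
  expect_true(all(perfect[c("accuracy", "sensitivity", "jaccard", "dsc")] == 1))

  missed <- metricsFromCounts(list(tp = 0, fp = 0, fn = 5, tn = 95, n = 100))
  expect_equal(missed$sensitivity, 0)
  expect_equal(missed$jaccard, 0)
  expect_equal(missed$dsc, 0)

  # truth-empty image: sensitivity is missing, never zero
  noTruth <- metricsFromCounts(list(tp = 0, fp = 3, fn = 0, tn = 97, n = 100))
  expect_true(is.na(noTruth$sensitivity))

  expect_error(metricsFromCounts(list(tp = 0, fp = 0, fn = 0, tn = 0, n = 0)),
               class = "mhseg_validation_error")
})

test_that("dsc = 2J/(1+J) and counts conserve pixels on random mask pairs", {
  set.seed(99)
  for (i in 1:100) {
    a <- randomMask(12, 12, runif(1, 0.1, 0.9))
    b <- randomMask(12, 12, runif(1, 0.1, 0.9))
    cc <- confusionCounts(a, b)
    expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 144)
    ev <- metricsFromCounts(cc)
    if (!is.na(ev$jaccard)) {
      expect_equal(ev$dsc, 2 * ev$jaccard / (1 + ev$jaccard), tolerance = 1e-12)
      expect_lte(ev$jaccard, ev$dsc)
    }
    # accuracy is symmetric under simultaneous complement of both masks
    cc2 <- confusionCounts(BinaryMask(1 - pixels(a)), BinaryMask(1 - pixels(b)))
    expect_equal(metricsFromCounts(cc2)$accuracy, ev$accuracy)
  }
})
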