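test_that("cct is the boundary gap at the central column times the pitch", {
  seg <- syntheticSegmentation(upper = rep(50, 100), lower = rep(84, 100))
  expect_equal(cctFromSegmentation(seg, 0.016), 34 * 0.016, tolerance = 1e-12)
  seg@validLower[45:55] <- FALSE
  expect_error(cctFromSegmentation(seg, 0.016, col = 50), "not jointly valid")
})

test_that("the pipeline recovers the configured central thickness", {
  fx <- restDefault()
  expect_equal(cctFromSegmentation(fx$seg, 0.016), 0.55, tolerance = 0.02)
})

test_that("highest concavity is the argmax with earliest-frame ties", {
  expect_identical(highestConcavity(c(0, 0, 0, 0)), 1L)
  expect_identical(highestConcavity(c(1, 2, 3, 4, 5)), 5L)
  expect_identical(highestConcavity(c(0, 3, 3, 1)), 2L)
  expect_error(highestConcavity(c(1, 2)), "at least 3")
})

test_that("peak distance measures the flanking-apex separation", {
  j <- 1:576; u <- j - 288.5
  # arc plus Gaussian depression whose analytic row-minima sit exactly
  # 75 columns either side of center: apexes 150 columns apart, equal rows
  w <- 50; ustar <- 75; R <- 487.5
  D <- w^2 * exp(ustar^2 / (2 * w^2)) / sqrt(R^2 - ustar^2)
  upper <- 45 + R - sqrt(R^2 - u^2) + D * exp(-u^2 / (2 * w^2))
  seg <- syntheticSegmentation(upper, upper + 34)
  res <- peakDistance(seg, 0.016)
  expect_equal(res$pd, 150 * 0.016, tolerance = 0.05)
  expect_lte(abs((res$apexCols[1L] + res$apexCols[2L]) / 2 - 288.5), 2)
  # convex rest boundary: undefined
  rest <- syntheticSegmentation(45 + 487.5 - sqrt(487.5^2 - (j - 288.5)^2),
    79 + 453.1 - sqrt(453.1^2 - (j - 288.5)^2))
  expect_error(peakDistance(rest, 0.016), "PD undefined")
})

test_that("peak distance from the pipeline matches the analytic apexes", {
  fx <- concaveDefault()
  res <- peakDistance(fx$seg, 0.016)
  truthSep <- diff(fx$truth@apexPositions) * 0.016
  expect_equal(res$pd, truthSep, tolerance = 2 * 0.016)
})

test_that("Bland-Altman limits and coverage behave as defined", {
  ba0 <- blandAltman(c(1, 2, 3), c(1, 2, 3))
  expect_identical(ba0$meanDiff, 0)
  expect_identical(ba0$lower, 0)
  expect_identical(ba0$fracOutside, 0)
  ba <- blandAltman(c(1, -1), c(0, 0))
  expect_equal(ba$meanDiff, 0)
  expect_equal(ba$upper, 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$lower, -2 * sqrt(2), tolerance = 1e-12)
  set.seed(99)
  d <- rnorm(1000)
  baG <- blandAltman(d, rep(0, 1000))
  expect_gte(1 - baG$fracOutside, 0.93)
  expect_lt(abs(baG$fracOutside - 0.046), 0.02)
  expect_error(blandAltman(1:3, 1:4), "lengths differ")
})

test_that("Pearson correlation has the textbook fixed points", {
  a <- c(1.5, 2.2, 4.8, 7.1, 9.0)
  expect_equal(pearsonR(a, 2 * a + 1), 1, tolerance = 1e-12)
  expect_equal(pearsonR(a, -a), -1, tolerance = 1e-12)
  set.seed(7)
  expect_lt(abs(pearsonR(rnorm(1e4), rnorm(1e4))), 0.05)
  # affine invariance
  b <- c(3, 1, 4, 1, 5)
  expect_equal(pearsonR(a, b), pearsonR(10 * a - 2, 0.5 * b + 7),
    tolerance = 1e-12)
  expect_equal(pearsonR(a, b), -pearsonR(-2 * a, b), tolerance = 1e-12)
  expect_error(pearsonR(c(1, 1, 1), a[1:3]), "zero variance")
})

test_that("pipeline CCT agrees with ground truth in Bland-Altman terms", {
  # sampled frames across the deformation cycle; differences in pixels
  cfg <- syntheticConfig(seed = 5L)
  ts <- c(1L, 35L, 60L, 70L, 80L, 105L, 135L)
  est <- tru <- numeric(length(ts))
  for (k in seq_along(ts)) {
    fr <- makeFrame(cfg, ts[k])
    seg <- segmentCornea(fr$frame)
    est[k] <- cctFromSegmentation(seg, 0.016) / 0.016
    tru[k] <- fr$truth@cctPx
  }
  expect_true(all(abs(est - tru) <= 2))
  ba <- blandAltman(est, tru)
  expect_lte(abs(ba$meanDiff), 1)
})

test_that("sequence metrics label the stages around the concavity", {
  cfg <- syntheticConfig(seed = 2L, noiseSigma = 0)
  ts <- c(1L, 55L, 70L, 85L, 140L)
  segs <- lapply(ts, function(t) segmentCornea(makeFrame(cfg, t)$frame))
  m <- sequenceMetrics(segs, 0.016)
  expect_identical(m$stage, c("before", "during", "during", "during", "after"))
  expect_identical(which.max(m$amplitudeMm), 3L)
  expect_false(is.na(m$pdMm[3L]))
  expect_true(all(m$cctMm > 0.5 & m$cctMm < 0.6, na.rm = TRUE))
})
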