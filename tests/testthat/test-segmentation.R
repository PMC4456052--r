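fullMask <- function(nr, nc)
  new("BinaryMask", mask = matrix(TRUE, nr, nc), provenance = "test")

test_that("a single-row symmetry ridge is recovered as a constant midline", {
  sym <- matrix(0, 50, 40); sym[23, ] <- 1
  ctr <- centerLine(sym, fullMask(50, 40))
  expect_lt(max(abs(ctr@fittedRows - 23)), 1e-8)
  expect_length(ctr@polyCoeffs, 6L)
})

test_that("per-column raw rows use the lower median of supra-threshold rows", {
  sym <- matrix(0, 50, 40)
  sym[c(10, 11, 15), ] <- 0.9          # odd count: median row 11
  ctr <- centerLine(sym, fullMask(50, 40))
  expect_true(all(ctr@rawRows == 11))
  sym2 <- matrix(0, 50, 40)
  sym2[c(10, 16), ] <- 0.9             # even count: lower median row 10
  ctr2 <- centerLine(sym2, fullMask(50, 40))
  expect_true(all(ctr2@rawRows == 10))
})

test_that("too few valid columns abort the midline fit", {
  sym <- matrix(0, 50, 40); sym[20, 1:4] <- 1
  expect_error(centerLine(sym, fullMask(50, 40)), "insufficient support")
})

test_that("boundary candidates split around the midline", {
  asym <- matrix(0, 100, 30)
  asym[40, ] <- 0.9; asym[70, ] <- 0.9
  ctr <- new("CenterLine", rawRows = rep(55, 30), rawIntensity = rep(1, 30),
    polyCoeffs = c(55, 0, 0, 0, 0, 0), colScale = c(15.5, 14.5),
    fittedRows = rep(55, 30), validCols = rep(TRUE, 30))
  for (mode in c("peak", "any")) {
    bp <- boundaryPoints(asym, ctr, bandThickness = 40, mode = mode)
    expect_true(all(abs(bp$upper - 40) < 1e-9))
    expect_true(all(abs(bp$lower - 70) < 1e-9))
  }
  # one-sided column: bright point only below the midline
  asym[40, 7] <- 0
  bp <- boundaryPoints(asym, ctr, bandThickness = 40)
  expect_false(bp$validUpper[7])
  expect_true(bp$validLower[7])
})

test_that("polynomial boundary fitting recovers exact and arc-like curves", {
  j <- 1:576
  x <- (j - 288.5) / 287.5
  exact <- 60 + 5 * x - 3 * x^2 + 2 * x^3 - x^4 + 0.5 * x^5
  expect_lt(max(abs(fitBoundary(exact) - exact)), 1e-8)
  arc <- 45 + 487.5 - sqrt(487.5^2 - (j - 288.5)^2)
  expect_lt(max(abs(fitBoundary(arc) - arc)), 0.5)
  # a single 20-px outlier among 400 valid columns barely moves the fit
  pert <- arc; pert[200] <- pert[200] + 20
  use <- rep(NA_real_, 576); use[88:487] <- pert[88:487]
  fitP <- fitBoundary(use)
  fitC <- fitBoundary(replace(use, 200, arc[200]))
  expect_lt(max(abs(fitP - fitC)[centralCols()]), 0.5)
})

test_that("spline boundary fitting tracks the concave deformation profile", {
  tr <- makeFrame(syntheticConfig(noiseSigma = 0), 70L)$truth
  cen <- centralCols()
  f <- fitBoundarySpline(ifelse(cen, upperRows(tr), NA_real_),
    allCols = 1:576)
  expect_lt(mean(abs(f - upperRows(tr))[cen]), 0.25)
  # robust pass: a 20-px artifact column does not drag the spline
  dirty <- ifelse(cen, upperRows(tr), NA_real_); dirty[300] <- dirty[300] + 20
  fD <- fitBoundarySpline(dirty, allCols = 1:576)
  expect_lt(max(abs(fD - f)[cen]), 0.5)
})

test_that("noise-free frames are segmented to sub-pixel accuracy", {
  fx <- restNoiseFree()
  cen <- centralCols()
  expect_lt(mean(abs(upperRows(fx$seg) - upperRows(fx$truth))[cen]), 0.5)
  expect_lt(mean(abs(lowerRows(fx$seg) - lowerRows(fx$truth))[cen]), 0.5)
  expect_lt(max(abs(centerRows(fx$seg) - centerRows(fx$truth))[cen]), 1.5)
})

test_that("default noisy frames stay within the 1-px boundary budget", {
  fx <- restDefault()
  cen <- centralCols()
  expect_lt(mean(abs(upperRows(fx$seg) - upperRows(fx$truth))[cen]), 1)
})

test_that("detached impurities do not degrade the segmentation", {
  arts <- defaultArtifacts(5L, seed = 31L)
  cfgC <- syntheticConfig(noiseSigma = 0, seed = 13L)
  cfgA <- syntheticConfig(noiseSigma = 0, seed = 13L, artifactSpec = arts)
  frC <- makeFrame(cfgC, 1L); frA <- makeFrame(cfgA, 1L)
  segC <- segmentCornea(frC$frame); segA <- segmentCornea(frA$frame)
  cen <- centralCols()
  eC <- mean(abs(upperRows(segC) - upperRows(frC$truth))[cen])
  eA <- mean(abs(upperRows(segA) - upperRows(frA$truth))[cen])
  expect_lt(eA, 0.5)
  expect_lt(abs(eA - eC), 0.25)
})

test_that("boundary ordering holds on valid unflagged columns", {
  for (fx in list(restDefault(), concaveDefault())) {
    seg <- fx$seg
    jv <- seg@validUpper & seg@validLower & !qualityFlags(seg)
    expect_gt(sum(jv), 300)
    expect_true(all(upperRows(seg)[jv] < centerRows(seg)[jv]))
    expect_true(all(centerRows(seg)[jv] < lowerRows(seg)[jv]))
  }
})

test_that("blank frames abort the segmentation", {
  expect_error(segmentCornea(matrix(0.4, 200, 576)), "empty frame")
})
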