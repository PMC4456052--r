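test_that("the radius normalization matches its printed branch constants", {
  expect_identical(normalizeRadius(-40), 0)
  expect_identical(normalizeRadius(100), 1)
  expect_equal(normalizeRadius(0), 0.315, tolerance = 1e-12)
  # R = 7 belongs to the second branch as printed ...
  expect_equal(normalizeRadius(7), 0.009 * 42, tolerance = 1e-12)
  # ... while the third branch opens at 0.3761 just above it
  expect_equal(normalizeRadius(7 + 1e-12), 0.3761, tolerance = 1e-9)
  expect_equal(normalizeRadius(10), 0.1333 * 3 + 0.3761, tolerance = 1e-12)
  expect_error(normalizeRadius(NaN), "finite")
})

test_that("normalization is monotone within branches with the printed jumps", {
  grid <- seq(-50, 50, length.out = 1e5)
  v <- normalizeRadius(grid)
  expect_true(all(v >= 0 & v <= 1))
  d <- diff(v)
  breaks <- findInterval(c(-35, 7, 10, 35), grid)
  interior <- setdiff(seq_along(d), c(breaks, breaks + 1L))
  expect_true(all(d[interior] >= 0))
  # the printed constants imply a 0.0019 dip entering the third branch
  expect_equal(normalizeRadius(7 + 1e-9) - normalizeRadius(7), -0.0019,
    tolerance = 1e-6)
  # and a 1e-4 step entering the fourth
  expect_equal(normalizeRadius(10 + 1e-9) - normalizeRadius(10), 1e-4,
    tolerance = 1e-6)
  # the continuous variant has no jumps anywhere
  vc <- normalizeRadius(grid, continuous = TRUE)
  expect_true(all(diff(vc) >= -1e-12))
})

test_that("the palette runs blue to red with monotone hue", {
  pal <- rainbowPalette()
  expect_identical(dim(pal), c(256L, 3L))
  expect_equal(drop(pseudoColor(0)), pal[1L, ], tolerance = 1e-12)
  expect_equal(drop(pseudoColor(1)), pal[256L, ], tolerance = 1e-12)
  expect_equal(unname(pal[1L, ]), c(0, 0, 1))
  expect_equal(unname(pal[256L, ]), c(1, 0, 0))
  hue <- grDevices::rgb2hsv(t(pal) * 255)[1L, ]
  expect_true(all(diff(hue) <= 1e-9))
  expect_warning(pseudoColor(1.2), "clamp")
})

test_that("rendering paints only the strip and leaves invalid columns gray", {
  fx <- restNoiseFree()
  prof <- curvatureProfile(upperRows(fx$seg), validCols = fx$seg@validUpper)
  out <- renderFrame(fx$frame, fx$seg, prof)
  expect_identical(dim(out), c(200L, 576L, 3L))
  # flagged end columns carry no color: all three channels equal the frame
  flagged <- which(qualityFlags(fx$seg))
  for (ch in 1:3)
    expect_identical(out[, flagged, ch], fx$frame[, flagged])
  # rows far from the boundary are untouched
  expect_identical(out[150:200, , 1L], fx$frame[150:200, ])
  # painted strip differs from the gray frame
  mid <- round(upperRows(fx$seg)[288])
  expect_gt(max(abs(out[mid, 288, ] - fx$frame[mid, 288])), 0.05)
})

test_that("a constant-radius cornea renders as a single hue band", {
  fx <- restNoiseFree()
  # exactly constant radius: the contract under test is the rendering
  prof <- new("CurvatureProfile", radiusMm = rep(7.8, 576),
    validCols = rep(TRUE, 576), halfWidth = 27, pixelPitch = 0.016)
  out <- renderFrame(fx$frame, fx$seg, prof)
  cols <- seq(150, 430, by = 20)
  rows <- round(upperRows(fx$seg)[cols])
  px <- t(vapply(seq_along(cols),
    function(i) out[rows[i], cols[i], ], numeric(3L)))
  H <- srgbToCam(px)$H
  expect_lt(diff(range(H)), 2)
})

test_that("a short sequence renders one frame per input frame", {
  cfg <- syntheticConfig(nFrames = 4L, noiseSigma = 0,
    deformAmplitudeMm = 0)
  out <- makeSequence(cfg)
  seg <- segmentCornea(frames(out$sequence)[[1L]])
  prof <- curvatureProfile(upperRows(seg), validCols = seg@validUpper)
  results <- replicate(4L, list(seg = seg, prof = prof), simplify = FALSE)
  outDir <- withr::local_tempdir()
  rv <- renderVideo(out$sequence, results, outDir = outDir)
  expect_length(rv$frames, 4L)
  expect_length(rv$paths, 4L)
  expect_true(all(file.exists(rv$paths)))
  expect_true(file.exists(file.path(outDir, "colorbar.png")))
  # identical rest frames render identically (shared palette/normalization)
  expect_identical(rv$frames[[1L]], rv$frames[[2L]])
})

test_that("strip width must be odd", {
  expect_error(fusionConfig(stripWidth = 20L), "odd")
  expect_silent(fusionConfig(stripWidth = 21L))
})
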