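# naivePhaseMaps (helper-oracles.R) is the independent per-pixel loop
# oracle for the vectorized maps.

smallCfg <- filterBankConfig(nScales = 3L, minWavelength = 4,
  scaleMultiplier = 2)

test_that("filters have no DC response and geometric center wavelengths", {
  bank <- buildBank(smallCfg, c(32L, 32L))
  expect_equal(bank$wavelengths, c(4, 8, 16))
  for (s in 1:3) for (o in 1:6)
    expect_identical(bank$filters[[s]][[o]][1L, 1L], 0)
  expect_error(buildBank(filterBankConfig(), c(32L, 32L)), "wavelength")
})

test_that("white-noise amplitudes shrink toward coarser scales", {
  # constant-octave log-Gabors intercept a frequency annulus whose area
  # scales with the square of the center frequency, so white noise excites
  # the fine scales hardest -- which is why the noise floor is propagated
  # down the wavelength progression
  set.seed(42)
  img <- matrix(rnorm(64 * 64), 64, 64)
  bank <- buildBank(smallCfg, c(64L, 64L))
  resp <- filterResponses(img, bank)
  med <- apply(resp@amplitude, 3L, median)
  expect_true(all(med > 0))
  expect_true(all(diff(med) < 0))
})

test_that("constant frames give zero quadrature responses", {
  bank <- buildBank(smallCfg, c(32L, 32L))
  resp <- filterResponses(matrix(0.7, 32, 32), bank)
  expect_lt(max(abs(resp@even)), 1e-12)
  expect_lt(max(abs(resp@odd)), 1e-12)
})

test_that("amplitude is the quadrature magnitude", {
  set.seed(1)
  bank <- buildBank(smallCfg, c(32L, 32L))
  resp <- filterResponses(matrix(runif(32 * 32), 32, 32), bank)
  expect_lt(max(abs(resp@amplitude^2 - (resp@even^2 + resp@odd^2))), 1e-9)
})

test_that("a bright ridge drives the even channel and the symmetry map", {
  img <- matrix(0, 64, 64); img[32, ] <- 1
  bank <- buildBank(smallCfg, c(64L, 64L))
  resp <- filterResponses(img, bank)
  # a horizontal ridge carries vertical frequency content: orientation 4
  # (angle pi/2) of the 6-orientation bank responds strongest
  e <- abs(resp@even[32, 32, 2L, 4L]); o <- abs(resp@odd[32, 32, 2L, 4L])
  expect_gt(e, 5 * o)
  pm <- phaseMaps(img, smallCfg)
  expect_identical(which.max(apply(symMap(pm), 1L, max)), 32L)
})

test_that("a step edge drives the odd channel and the asymmetry map", {
  img <- matrix(0, 64, 64); img[, 33:64] <- 1
  bank <- buildBank(smallCfg, c(64L, 64L))
  resp <- filterResponses(img, bank)
  # a vertical edge carries horizontal frequency content: orientation 1
  oa <- abs(resp@odd[32, 33, 2L, 1L]); ea <- abs(resp@even[32, 33, 2L, 1L])
  expect_gt(oa, ea)
  # localization check on a wrap-free resolved plateau (periodic FFT would
  # add a second edge at the image boundary of a lone step); the acquisition
  # noise level keeps the energy-normalized measure from flaring up in the
  # empty far field
  prof <- pnorm(((1:192) - 64.5) / 1.5) * pnorm((128.5 - (1:192)) / 1.5)
  set.seed(3)
  img2 <- matrix(rep(prof, each = 64), 64, 192) +
    matrix(rnorm(64 * 192, 0, 0.01), 64, 192)
  pm <- phaseMaps(img2, smallCfg)
  peakCol <- which.max(colMeans(asymMap(pm)))
  expect_lte(min(abs(peakCol - c(64.5, 128.5))), 1)
})

test_that("zero input yields exactly zero maps", {
  z <- matrix(0, 32, 32)
  pm <- phaseMaps(z, smallCfg)
  expect_identical(max(symMap(pm)), 0)
  expect_identical(max(asymMap(pm)), 0)
})

test_that("maps stay within [0, 1] on random frames", {
  set.seed(9)
  for (i in 1:3) {
    pm <- phaseMaps(matrix(runif(48 * 48), 48, 48), smallCfg)
    expect_gte(min(symMap(pm)), 0); expect_lte(max(symMap(pm)), 1)
    expect_gte(min(asymMap(pm)), 0); expect_lte(max(asymMap(pm)), 1)
  }
})

test_that("asymmetry vanishes on a mirror-symmetry axis", {
  rr <- matrix(seq_len(63), 63, 64)
  img <- exp(-(rr - 32)^2 / 18)  # even Gaussian ridge about row 32
  pm <- phaseMaps(img, smallCfg)
  expect_lt(max(asymMap(pm)[32, 5:60]), 0.05)
})

test_that("vectorized maps equal the per-pixel loop oracle", {
  set.seed(3)
  img <- matrix(runif(32 * 32), 32, 32)
  img[10:14, ] <- img[10:14, ] + 1
  bank <- buildBank(smallCfg, c(32L, 32L))
  resp <- filterResponses(img, bank)
  oracle <- naivePhaseMaps(resp, smallCfg)
  expect_lt(max(abs(phaseSymmetry(resp, smallCfg) - oracle$sym)), 1e-10)
  expect_lt(max(abs(phaseAsymmetry(resp, smallCfg) - oracle$asym)), 1e-10)
  pm <- phaseMaps(img, smallCfg, bank = bank)
  expect_lt(max(abs(symMap(pm) - oracle$sym)), 1e-10)
  expect_lt(max(abs(asymMap(pm) - oracle$asym)), 1e-10)
})

test_that("maps are invariant to global intensity scaling when T = 0", {
  cfg0 <- filterBankConfig(nScales = 3L, minWavelength = 4,
    scaleMultiplier = 2, noiseK = 0, epsilon = 1e-12)
  set.seed(5)
  img <- matrix(runif(48 * 48), 48, 48)
  a <- phaseMaps(img, cfg0); b <- phaseMaps(2 * img, cfg0)
  expect_lt(max(abs(symMap(a) - symMap(b))), 1e-6)
  expect_lt(max(abs(asymMap(a) - asymMap(b))), 1e-6)
})
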