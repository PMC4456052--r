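# Shared fixtures built in code.  Central two-thirds column window of the
# default 576-column frame, used for all quantitative boundary checks
# (the image ends are flagged unreliable by design).

centralCols <- function(nc = 576L) {
  j <- seq_len(nc)
  j >= nc / 6 & j <= 5 * nc / 6
}

# Cache expensive per-frame pipeline results within one test run.
.fixtureCache <- new.env(parent = emptyenv())

cachedSegmentation <- function(key, config, t) {
  if (is.null(.fixtureCache[[key]])) {
    fr <- makeFrame(config, t)
    .fixtureCache[[key]] <- list(frame = fr$frame, truth = fr$truth,
      seg = segmentCornea(fr$frame))
  }
  .fixtureCache[[key]]
}

restNoiseFree <- function() {
  cachedSegmentation("restNoiseFree", syntheticConfig(noiseSigma = 0), 1L)
}

restDefault <- function() {
  cachedSegmentation("restDefault", syntheticConfig(), 1L)
}

concaveDefault <- function() {
  cachedSegmentation("concaveDefault", syntheticConfig(), 70L)
}

# Small segmentation object with prescribed boundary rows, for metric
# tests that do not need the imaging pipeline.
syntheticSegmentation <- function(upper, lower, center = (upper + lower) / 2) {
  nc <- length(upper)
  ctr <- new("CenterLine", rawRows = center, rawIntensity = rep(1, nc),
    polyCoeffs = c(mean(center), 0, 0, 0, 0, 0), colScale = c(0, 1),
    fittedRows = center, validCols = rep(TRUE, nc))
  new("SegmentationResult", center = ctr, upperRows = upper,
    lowerRows = lower, validUpper = rep(TRUE, nc),
    validLower = rep(TRUE, nc), qualityFlags = rep(FALSE, nc))
}
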