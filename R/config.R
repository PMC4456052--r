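## Nested pipeline configuration.  Every stage constant lives here; the
## defaults are the working values of the method: 10 x 60 closing element,
## 1/3 area ratio, symmetry threshold 0.1, degree-5 polynomial fits,
## 27-px curvature half-window, 21-px fusion strip, 0.016 mm pixel pitch.

.configSchema <- list(
  io = c("pixelPitch", "bitDepth"),
  phase = c("nScales", "nOrientations", "minWavelength", "scaleMultiplier",
    "sigmaOnF", "noiseK", "epsilon", "dThetaOnSigma"),
  preprocess = c("se", "ratio", "binarization", "maskGrow"),
  segmentation = c("tauSym", "tauAsym", "degree", "weighted",
    "searchFactor", "candidateMode", "refine", "boundaryModel",
    "boundaryDf"),
  curvature = c("halfWidth", "pixelPitch"),
  fusion = c("stripWidth", "palette", "continuousNormalization",
    "useChroma", "LA", "Yb", "surround"),
  metrics = c("refFrame", "stageThresholdMm", "prominence"),
  synthetic = c())

#' Pipeline configuration
#'
#' Builds the nested configuration consumed by [segmentCornea()] and
#' [runPipeline()].  Blocks: `io`, `phase`, `preprocess`, `segmentation`,
#' `curvature`, `fusion`, `metrics`.  Unknown keys are rejected.
#'
#' @param ... named blocks (lists) overriding individual defaults, e.g.
#'   `segmentation = list(tauAsym = 0.25)`.
#' @return list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    io = list(pixelPitch = 0.016, bitDepth = 16L),
    phase = list(nScales = 4L, nOrientations = 6L, minWavelength = 4,
      scaleMultiplier = 2.1, sigmaOnF = 0.55, noiseK = 2, epsilon = 1e-4,
      dThetaOnSigma = 1.3),
    preprocess = list(se = c(10L, 60L), ratio = 1 / 3,
      binarization = "otsu", maskGrow = 8L),
    segmentation = list(tauSym = 0.1, tauAsym = 0.3, degree = 5L,
      weighted = TRUE, searchFactor = 0.75, candidateMode = "peak",
      refine = TRUE, boundaryModel = "spline", boundaryDf = 15),
    curvature = list(halfWidth = 27L, pixelPitch = 0.016),
    fusion = list(stripWidth = 21L, palette = "rainbow",
      continuousNormalization = FALSE, useChroma = FALSE, LA = 60,
      Yb = 20, surround = "average"),
    metrics = list(refFrame = 1L, stageThresholdMm = 0.15,
      prominence = 0.5))
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("overrides must be named blocks")
    for (blk in names(over)) {
      if (!blk %in% names(.configSchema))
        stop(sprintf("unknown config block '%s'", blk))
      vals <- over[[blk]]
      bad <- setdiff(names(vals), .configSchema[[blk]])
      if (length(bad))
        stop(sprintf("unknown key(s) in block '%s': %s", blk,
          paste(bad, collapse = ", ")))
      cfg[[blk]][names(vals)] <- vals
    }
  }
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' The JSON file holds (a subset of) the nested blocks of
#' [pipelineConfig()]; values merge over the defaults and unknown keys are
#' rejected.
#'
#' @param path JSON file path.
#' @return list of class `"PipelineConfig"`.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipelineConfig, raw)
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("PipelineConfig with blocks:", paste(names(unclass(x)), collapse = ", "),
    "\n")
  invisible(x)
}

## Fusion block -> FusionConfig
fusionFromPipeline <- function(config) {
  fb <- config$fusion
  fusionConfig(stripWidth = fb$stripWidth,
    continuousNormalization = fb$continuousNormalization,
    useChroma = fb$useChroma,
    vc = viewingConditions(LA = fb$LA, Yb = fb$Yb, surround = fb$surround))
}
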