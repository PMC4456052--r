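## Synthetic Corvis-ST-style frame and sequence generator with exact
## analytic ground truth.  Geometry: the anterior boundary at rest is a
## circular arc (apex toward the top of the image); the posterior boundary
## is the concentric arc one central-thickness below.  The air-puff
## deformation displaces both boundaries downward by a Gaussian-in-column
## indentation whose amplitude follows a raised-cosine pulse in time.

#' Configuration for the synthetic frame generator
#'
#' Builds a validated configuration for [makeFrame()] / [makeSequence()].
#' Defaults emulate a Corvis ST acquisition: 200 x 576 px frames at
#' 0.016 mm/px, 140 frames, a 7.8 mm anterior radius and 0.55 mm central
#' thickness, with a 1 mm peak apex indentation at frame 70.
#'
#' @param nRows,nCols frame size in pixels.
#' @param pixelPitch mm per pixel.
#' @param nFrames frames per acquisition.
#' @param anteriorRadiusMm signed anterior radius at rest (positive =
#'   convex toward the camera).
#' @param cctMm central corneal thickness in mm.
#' @param bandSigma Gaussian width (px) of the band's edge roll-off,
#'   measured along image columns.
#' @param centerBump relative amplitude of the intensity peak on the band
#'   midline (makes the noise-free per-column argmax sit exactly on the
#'   midline).
#' @param bandIntensity,background band and background intensity levels.
#' @param apexRow row of the anterior apex at rest.
#' @param illumGradient length-2 multiplicative illumination factors at the
#'   left and right image edge (linear ramp in between).
#' @param noiseSigma additive Gaussian noise standard deviation.
#' @param artifactSpec data.frame of artifact primitives, e.g. from
#'   [defaultArtifacts()]; `NULL` for none.
#' @param deformAmplitudeMm peak apex displacement in mm.
#' @param deformSigmaPx Gaussian column-width (px) of the indentation.
#' @param deformHalfWidthFrames half-duration (frames) of the raised-cosine
#'   deformation pulse.
#' @param concavityFrame frame index (1-based) of the highest concavity.
#' @param seed RNG seed; the same (config, seed) yields bit-identical output.
#' @return a list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(nRows = 200L, nCols = 576L, pixelPitch = 0.016,
    nFrames = 140L, anteriorRadiusMm = 7.8, cctMm = 0.55, bandSigma = 2,
    centerBump = 0.05, bandIntensity = 0.75, background = 0.03,
    apexRow = 45, illumGradient = c(0.85, 1), noiseSigma = 0.01,
    artifactSpec = NULL, deformAmplitudeMm = 1.0, deformSigmaPx = 60,
    deformHalfWidthFrames = 35, concavityFrame = 70L, seed = 1L) {
  cfg <- list(nRows = as.integer(nRows), nCols = as.integer(nCols),
    pixelPitch = pixelPitch, nFrames = as.integer(nFrames),
    anteriorRadiusMm = anteriorRadiusMm, cctMm = cctMm,
    bandSigma = bandSigma, centerBump = centerBump,
    bandIntensity = bandIntensity, background = background,
    apexRow = apexRow, illumGradient = illumGradient,
    noiseSigma = noiseSigma, artifactSpec = artifactSpec,
    deformAmplitudeMm = deformAmplitudeMm, deformSigmaPx = deformSigmaPx,
    deformHalfWidthFrames = deformHalfWidthFrames,
    concavityFrame = as.integer(concavityFrame), seed = as.integer(seed))
  if (cfg$nRows <= 0L || cfg$nCols <= 0L || cfg$nFrames <= 0L)
    stop("nRows, nCols and nFrames must be positive")
  if (cfg$pixelPitch <= 0) stop("pixelPitch must be positive")
  if (cfg$anteriorRadiusMm <= 0) stop("anteriorRadiusMm must be positive")
  if (cfg$cctMm <= 0 || cfg$cctMm >= cfg$anteriorRadiusMm)
    stop("cctMm must lie in (0, anteriorRadiusMm)")
  if (cfg$bandSigma <= 0) stop("bandSigma must be positive")
  if (length(cfg$illumGradient) != 2L || any(cfg$illumGradient <= 0) ||
      any(cfg$illumGradient > 1))
    stop("illumGradient must be two factors in (0, 1]")
  if (cfg$deformAmplitudeMm < 0) stop("deformAmplitudeMm must be >= 0")
  if (cfg$deformSigmaPx <= 0) stop("deformSigmaPx must be positive")
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' @export
print.SyntheticConfig <- function(x, ...) {
  cat(sprintf(paste0("SyntheticConfig: %d x %d px, %d frames, R = %.2f mm, ",
    "cct = %.2f mm,\n  deform %.2f mm peaking at frame %d, noise %.3f, ",
    "%d artifact(s), seed %d\n"),
    x$nRows, x$nCols, x$nFrames, x$anteriorRadiusMm, x$cctMm,
    x$deformAmplitudeMm, x$concavityFrame, x$noiseSigma,
    if (is.null(x$artifactSpec)) 0L else nrow(x$artifactSpec), x$seed))
  invisible(x)
}

#' Random eyelash/tear artifact primitives
#'
#' Generates `n` thin bright curved strokes (quadratic Bezier segments,
#' 2-4 px wide) in the region above the corneal band.  Detached strokes
#' stay clear of the band; attached ones end on it, emulating an eyelash
#' touching the cornea.
#'
#' @param n number of artifacts.
#' @param config a [syntheticConfig()].
#' @param attached logical, recycled to length `n`.
#' @param seed RNG seed for artifact placement.
#' @return data.frame usable as `artifactSpec`.
#' @export
defaultArtifacts <- function(n = 5L, config = syntheticConfig(),
    attached = FALSE, seed = 99L) {
  attached <- rep_len(attached, n)
  withRNG(seed, {
    colMid <- stats::runif(n, 0.15 * config$nCols, 0.85 * config$nCols)
    len <- stats::runif(n, 40, 90)
    ang <- stats::runif(n, -0.5, 0.5)
    bandTop <- config$apexRow
    ## detached strokes keep >= 18 px clearance above the band so the
    ## 10-row closing element cannot bridge them onto the cornea
    row0 <- stats::runif(n, 8, max(10, bandTop - 28))
    bend <- stats::runif(n, -8, 8)
    width <- stats::runif(n, 2, 4)
    intensity <- stats::runif(n, 0.5, 0.85)
    dr <- sin(ang) * len; dc <- cos(ang) * len
    row2 <- ifelse(attached, bandTop + 2,
      pmin(pmax(row0 + dr, 5), bandTop - 18))
    data.frame(type = ifelse(attached, "eyelash_attached", "eyelash"),
      row0 = row0, col0 = colMid - dc / 2,
      row1 = (row0 + row2) / 2 + bend, col1 = colMid,
      row2 = row2, col2 = colMid + dc / 2,
      width = width, intensity = intensity, attached = attached)
  })
}

## Evaluate the deformation pulse (apex displacement in px) at frame t.
deformationPx <- function(config, t) {
  ampPx <- config$deformAmplitudeMm / config$pixelPitch
  hw <- config$deformHalfWidthFrames
  dt <- t - config$concavityFrame
  if (abs(dt) >= hw) return(0)
  ampPx * cos(pi * dt / (2 * hw))^2
}

## Analytic boundary geometry at displacement d (px).  Returns per-column
## upper/lower/center rows, signed radius (mm), and helpers.
syntheticGeometry <- function(config, d) {
  Rpx <- config$anteriorRadiusMm / config$pixelPitch
  cctPx <- config$cctMm / config$pixelPitch
  cc <- (config$nCols + 1) / 2
  u <- seq_len(config$nCols) - cc
  w <- config$deformSigmaPx
  if (max(abs(u)) >= Rpx - cctPx)
    stop("anteriorRadiusMm too small: the posterior arc does not span nCols")
  G <- exp(-u^2 / (2 * w^2))
  upper <- config$apexRow + Rpx - sqrt(Rpx^2 - u^2) + d * G
  lower <- config$apexRow + Rpx - sqrt((Rpx - cctPx)^2 - u^2) + d * G
  center <- (upper + lower) / 2
  ## signed curvature of the anterior boundary r(j):
  ## r'  = u/sqrt(R^2-u^2) - d u/w^2 G
  ## r'' = R^2/(R^2-u^2)^(3/2) - d/w^2 (1 - u^2/w^2) G
  r1 <- u / sqrt(Rpx^2 - u^2) - d * u / w^2 * G
  r2 <- Rpx^2 / (Rpx^2 - u^2)^1.5 - d / w^2 * (1 - u^2 / w^2) * G
  radiusMm <- ifelse(r2 == 0, Inf,
    config$pixelPitch * (1 + r1^2)^1.5 / r2)
  list(upper = upper, lower = lower, center = center, radiusMm = radiusMm,
    u = u, cc = cc, Rpx = Rpx, w = w, d = d)
}

## Columns of the two forward apexes flanking the central depression, found
## on the analytic anterior curve (NULL when the apex is not concave).
apexColumns <- function(geom) {
  d <- geom$d; w <- geom$w; Rpx <- geom$Rpx
  if (d <= w^2 / Rpx) return(numeric(0))
  h <- function(u) d / w^2 * exp(-u^2 / (2 * w^2)) - 1 / sqrt(Rpx^2 - u^2)
  hiOK <- min(6 * w, 0.99 * Rpx)
  if (h(hiOK) >= 0) return(numeric(0))
  us <- stats::uniroot(h, c(1e-9, hiOK), tol = 1e-10)$root
  geom$cc + c(-us, us)
}

## Stamp one Bezier stroke onto the frame (bright, max-composited).
stampArtifact <- function(img, a) {
  s <- seq(0, 1, length.out = 240)
  br <- (1 - s)^2 * a$row0 + 2 * s * (1 - s) * a$row1 + s^2 * a$row2
  bc <- (1 - s)^2 * a$col0 + 2 * s * (1 - s) * a$col1 + s^2 * a$col2
  pad <- 3 * a$width
  r0 <- max(1L, floor(min(br) - pad)); r1 <- min(nrow(img), ceiling(max(br) + pad))
  c0 <- max(1L, floor(min(bc) - pad)); c1 <- min(ncol(img), ceiling(max(bc) + pad))
  if (r0 > r1 || c0 > c1) return(img)
  rr <- r0:r1; cols <- c0:c1
  d2 <- matrix(Inf, length(rr), length(cols))
  for (i in seq_along(s)) {
    d2 <- pmin(d2, outer((rr - br[i])^2, (cols - bc[i])^2, `+`))
  }
  field <- a$intensity * exp(-d2 / (2 * (a$width / 2)^2))
  img[rr, cols] <- pmax(img[rr, cols], field)
  img
}

#' Render one synthetic frame with its exact ground truth
#'
#' @param config a [syntheticConfig()].
#' @param t frame index (1-based, `1 <= t <= nFrames`).
#' @return list with elements `frame` (numeric matrix in \[0,1\]) and
#'   `truth` (a \linkS4class{GroundTruth}).
#' @examples
#' fr <- makeFrame(syntheticConfig(noiseSigma = 0), t = 1)
#' dim(fr$frame)
#' @export
makeFrame <- function(config, t = 1L) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (t < 1L || t > config$nFrames)
    stop("t must lie in 1..nFrames")
  d <- deformationPx(config, t)
  geom <- syntheticGeometry(config, d)
  if (min(geom$upper) - 3 * config$bandSigma < 1)
    stop("apexRow too small: band leaves the image at the top")
  if (max(geom$lower) + 3 * config$bandSigma > config$nRows)
    stop(paste("band leaves the image at the bottom;",
      "reduce deformAmplitudeMm or apexRow, or increase nRows"))
  nr <- config$nRows; nc <- config$nCols
  rr <- matrix(seq_len(nr), nr, nc)
  upM <- matrix(geom$upper, nr, nc, byrow = TRUE)
  loM <- matrix(geom$lower, nr, nc, byrow = TRUE)
  ctM <- matrix(geom$center, nr, nc, byrow = TRUE)
  sig <- config$bandSigma
  g <- stats::pnorm((rr - upM) / sig) * stats::pnorm((loM - rr) / sig)
  sigC <- (loM - upM) / 3
  bump <- 1 + config$centerBump * exp(-(rr - ctM)^2 / (2 * sigC^2))
  img <- config$background + config$bandIntensity * g * bump
  ill <- seq(config$illumGradient[1L], config$illumGradient[2L],
    length.out = nc)
  img <- img * matrix(ill, nr, nc, byrow = TRUE)
  if (!is.null(config$artifactSpec) && nrow(config$artifactSpec) > 0L) {
    for (i in seq_len(nrow(config$artifactSpec)))
      img <- stampArtifact(img, config$artifactSpec[i, , drop = FALSE])
  }
  if (config$noiseSigma > 0) {
    img <- withRNG(frameSeed(config$seed, t),
      img + matrix(stats::rnorm(nr * nc, 0, config$noiseSigma), nr, nc))
  }
  img <- pmin(pmax(img, 0), 1)
  apexCol <- which.min(abs(seq_len(nc) - geom$cc))
  stage <- frameStage(config, t, d, geom)
  truth <- new("GroundTruth", upperRows = geom$upper,
    lowerRows = geom$lower, centerRows = geom$center,
    radiusMm = geom$radiusMm,
    cctPx = geom$lower[apexCol] - geom$upper[apexCol],
    apexPositions = apexColumns(geom), apexDisplacementPx = d,
    stage = stage,
    artifacts = if (is.null(config$artifactSpec)) data.frame()
      else config$artifactSpec)
  list(frame = img, truth = truth)
}

## Stage labels by displacement thresholding: "during" while the apex
## displacement exceeds the concavity-onset displacement w^2/Rpx (i.e.
## exactly while the analytic apex radius is negative), "before"/"after"
## on either side of the concavity frame otherwise.
frameStage <- function(config, t, d, geom) {
  if (d > geom$w^2 / geom$Rpx) "during"
  else if (t <= config$concavityFrame) "before"
  else "after"
}

frameSeed <- function(seed, t)
  ((abs(seed) %% 2000000L) * 1009L + as.integer(t)) %% 2147483647L

#' Render a full synthetic deformation sequence
#'
#' Applies [makeFrame()] at every frame index.  The apex displacement is a
#' raised-cosine pulse peaking at `concavityFrame`, so the sequence runs
#' convex (before) -> concave (during) -> convex (after).
#'
#' @param config a [syntheticConfig()].
#' @return list with `sequence` (a \linkS4class{CorvisSequence}) and
#'   `truth` (list of \linkS4class{GroundTruth}, one per frame).
#' @export
makeSequence <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  out <- lapply(seq_len(config$nFrames), function(t) makeFrame(config, t))
  seqObj <- new("CorvisSequence", frames = lapply(out, `[[`, "frame"),
    pixelPitch = config$pixelPitch,
    metadata = list(generator = "corvistopo synthetic", config = config))
  list(sequence = seqObj, truth = lapply(out, `[[`, "truth"))
}

## Run expr with a local RNG seeded at `seed`, restoring the caller's RNG.
withRNG <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
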