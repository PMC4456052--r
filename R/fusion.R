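## Curvature visualization: the signed radius is squeezed through a
## piecewise normalization that spends most of the palette on the
## physiological 7-10 mm range while still resolving the concave (negative)
## radii reached during deformation; the normalized value indexes a rainbow
## palette, and the pseudo-color strip is fused with the grayscale anatomy
## in CIECAM02 space (J from the gray image, H and s from the color).

#' Piecewise nonlinear radius normalization
#'
#' Maps a signed radius (mm) into \[0, 1\]:
#' \preformatted{
#'   0                        R <= -35
#'   0.009  (R + 35)     -35 < R <=  7
#'   0.1333 (R - 7) + 0.3761   7 < R <= 10
#'   0.009  (R - 10) + 0.7761 10 < R <= 35
#'   1                        R >  35
#' }
#' The breakpoint constants are used exactly as stated, including the small
#' jumps they imply at R = 7 (0.378 vs 0.3761) and R = 35 (1.0011, clamped);
#' `continuous = TRUE` substitutes junction-matched slopes instead.
#'
#' @param R numeric signed radii in mm (finite).
#' @param continuous use the continuity-corrected variant.
#' @return numeric in \[0, 1\].
#' @examples
#' normalizeRadius(c(-40, 0, 7.8, 100))
#' @export
normalizeRadius <- function(R, continuous = FALSE) {
  if (any(!is.finite(R))) stop("R must be finite")
  out <- numeric(length(R))
  b2 <- -35 < R & R <= 7
  b3 <- 7 < R & R <= 10
  b4 <- 10 < R & R <= 35
  if (continuous) {
    out[b2] <- 0.3761 / 42 * (R[b2] + 35)
    out[b3] <- (0.7761 - 0.3761) / 3 * (R[b3] - 7) + 0.3761
    out[b4] <- (1 - 0.7761) / 25 * (R[b4] - 10) + 0.7761
  } else {
    out[b2] <- 0.009 * (R[b2] + 35)
    out[b3] <- 0.1333 * (R[b3] - 7) + 0.3761
    out[b4] <- 0.009 * (R[b4] - 10) + 0.7761
  }
  out[R > 35] <- 1
  pmin(pmax(out, 0), 1)
}

.paletteCache <- new.env(parent = emptyenv())

#' The shipped rainbow palette table
#'
#' 256 sRGB rows from pure blue (index 0) to pure red (index 255), constant
#' saturation and value, hue decreasing monotonically.
#'
#' @return 256 x 3 numeric matrix in \[0, 1\].
#' @export
rainbowPalette <- function() {
  if (is.null(.paletteCache$tab)) {
    f <- system.file("extdata", "rainbow256.csv", package = "corvistopo")
    tab <- utils::read.csv(f)
    .paletteCache$tab <- as.matrix(tab[, c("r", "g", "b")]) / 255
  }
  .paletteCache$tab
}

#' Map normalized curvature values to pseudo-color
#'
#' Linear interpolation between the 256 entries of the shipped table;
#' 0 maps exactly to the blue endpoint, 1 to the red endpoint.
#' Out-of-range inputs are clamped with a warning.
#'
#' @param rnew numeric values, nominally in \[0, 1\].
#' @param palette palette matrix (default [rainbowPalette()]).
#' @return n x 3 sRGB matrix.
#' @export
pseudoColor <- function(rnew, palette = rainbowPalette()) {
  if (any(rnew < 0 | rnew > 1, na.rm = TRUE)) {
    warning("rnew outside [0, 1]; clamping")
    rnew <- pmin(pmax(rnew, 0), 1)
  }
  np <- nrow(palette)
  pos <- rnew * (np - 1)
  i <- pmin(floor(pos), np - 2)
  f <- pos - i
  (1 - f) * palette[i + 1L, , drop = FALSE] +
    f * palette[i + 2L, , drop = FALSE]
}

#' Fusion configuration
#'
#' @param stripWidth odd strip width in px centered on the anterior
#'   boundary (default 21).
#' @param continuousNormalization use the continuity-corrected
#'   [normalizeRadius()] variant.
#' @param useChroma fuse CIECAM02 chroma C instead of saturation s.
#' @param vc a [viewingConditions()].
#' @return list of class `"FusionConfig"`.
#' @export
fusionConfig <- function(stripWidth = 21L, continuousNormalization = FALSE,
    useChroma = FALSE, vc = viewingConditions()) {
  stripWidth <- as.integer(stripWidth)
  if (stripWidth < 3L || stripWidth %% 2L == 0L)
    stop("stripWidth must be odd and >= 3")
  structure(list(stripWidth = stripWidth,
    continuousNormalization = continuousNormalization,
    useChroma = useChroma, vc = vc),
    class = "FusionConfig")
}

#' Fuse a grayscale strip with a pseudo-color strip in CIECAM02 space
#'
#' Per pixel, the output takes its lightness J from the gray value
#' (forward-transformed as the achromatic sRGB triple (g,g,g)) and its hue
#' quadrature H and saturation s from the pseudo-color pixel, then inverts
#' back to sRGB.
#'
#' @param grayStrip numeric matrix of intensities in \[0, 1\].
#' @param colorStrip array `dim(grayStrip) x 3` of sRGB values.
#' @param vc a [viewingConditions()].
#' @param useChroma fuse chroma C instead of saturation s.
#' @return array `dim(grayStrip) x 3`, with attribute `"clipFraction"`.
#' @export
fuseStrip <- function(grayStrip, colorStrip, vc = viewingConditions(),
    useChroma = FALSE) {
  d <- dim(grayStrip)
  if (!identical(dim(colorStrip), c(d, 3L)) &&
      !identical(dim(colorStrip), as.integer(c(d, 3))))
    stop("grayStrip and colorStrip shapes differ")
  g <- as.vector(grayStrip)
  camG <- srgbToCam(cbind(g, g, g), vc)
  cs <- matrix(colorStrip, ncol = 3L)
  camC <- srgbToCam(cs, vc)
  if (useChroma) {
    ## rebuild s from the color's C at the gray's J
    Q <- (4 / vc$c) * sqrt(camG$J / 100) * (vc$Aw + 4) * vc$FL^0.25
    M <- camC$C * vc$FL^0.25
    sFuse <- ifelse(Q > 0, 100 * sqrt(M / Q), 0)
  } else sFuse <- camC$s
  rgb <- camToSrgb(camG$J, camC$H, sFuse, vc)
  out <- array(rgb, c(d, 3L))
  attr(out, "clipFraction") <- attr(rgb, "clipFraction")
  attr(out, "clipped") <- matrix(attr(rgb, "clipped"), d[1L], d[2L])
  out
}

#' Render the curvature topography of one frame
#'
#' Extracts the strip of `stripWidth` rows centered on the fitted anterior
#' boundary, expands the per-column normalized radius to the strip width,
#' pseudo-colors it, fuses it with the grayscale strip, and pastes the
#' result back into an RGB copy of the frame.  Columns with an invalid
#' radius stay gray.
#'
#' @param frame numeric matrix in \[0, 1\].
#' @param seg a \linkS4class{SegmentationResult} of the frame.
#' @param prof a \linkS4class{CurvatureProfile} of the anterior boundary.
#' @param cfg a [fusionConfig()].
#' @return `nrow x ncol x 3` sRGB array with attribute `"clipFraction"`.
#' @export
renderFrame <- function(frame, seg, prof, cfg = fusionConfig()) {
  nr <- nrow(frame); nc <- ncol(frame)
  hw <- (cfg$stripWidth - 1L) %/% 2L
  rnew <- normalizeRadius(
    ifelse(prof@validCols, prof@radiusMm, 0),
    continuous = cfg$continuousNormalization)
  colorCols <- prof@validCols & !seg@qualityFlags
  out <- array(rep(frame, 3L), c(nr, nc, 3L))
  clipN <- 0L; totN <- 0L
  ctrRows <- round(seg@upperRows)
  usable <- which(colorCols)
  if (length(usable)) {
    offs <- (-hw):hw
    truncated <- FALSE
    ## gather the strip as a (stripWidth x nUsable) matrix
    rowsIdx <- outer(offs, ctrRows[usable], `+`)
    bad <- rowsIdx < 1L | rowsIdx > nr
    if (any(bad)) { truncated <- TRUE; rowsIdx[bad] <- pmin(pmax(rowsIdx[bad], 1L), nr) }
    flat <- rowsIdx + (rep(usable, each = length(offs)) - 1L) * nr
    grayStrip <- matrix(frame[flat], length(offs), length(usable))
    colStrip <- pseudoColor(rep(rnew[usable], each = length(offs)))
    colArr <- array(colStrip, c(length(offs), length(usable), 3L))
    fused <- fuseStrip(grayStrip, colArr, cfg$vc, useChroma = cfg$useChroma)
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[flat[!bad]] <- fused[, , ch][!bad]
      out[, , ch] <- plane
    }
    if (truncated) warning("strip truncated at the frame border")
    clipN <- attr(fused, "clipFraction") * length(flat)
    totN <- length(flat)
  }
  attr(out, "clipFraction") <- if (totN) clipN / totN else 0
  out
}

#' Render a full topography sequence
#'
#' One rendered frame per input frame, under a single palette and
#' normalization shared across the whole video (identical radii map to
#' identical colors in every frame).  Frames are written as PNGs
#' (`frame_0001.png`, ...) together with a shared colorbar legend.
#'
#' @param sequence a \linkS4class{CorvisSequence}.
#' @param results list with per-frame `seg` and `prof` entries, as produced
#'   by [runPipeline()].
#' @param cfg a [fusionConfig()].
#' @param outDir output directory; `NULL` skips writing and returns the
#'   rendered arrays.
#' @return invisibly, a list of rendered arrays (and written paths when
#'   `outDir` is given).
#' @export
renderVideo <- function(sequence, results, cfg = fusionConfig(),
    outDir = NULL) {
  stopifnot(is(sequence, "CorvisSequence"))
  if (length(results) != nFrames(sequence))
    stop("one result per frame required")
  rendered <- vector("list", nFrames(sequence))
  paths <- character(0)
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(rendered)) {
    rendered[[i]] <- renderFrame(frames(sequence)[[i]],
      results[[i]]$seg, results[[i]]$prof, cfg)
    if (!is.null(outDir)) {
      p <- file.path(outDir, sprintf("frame_%04d.png", i))
      png::writePNG(rendered[[i]], p)
      paths <- c(paths, p)
    }
  }
  if (!is.null(outDir)) {
    cb <- colorbarImage(cfg)
    png::writePNG(cb, file.path(outDir, "colorbar.png"))
  }
  invisible(list(frames = rendered, paths = paths))
}

#' Shared colorbar legend image
#'
#' @param cfg a [fusionConfig()].
#' @param width,height legend size in px.
#' @return `height x width x 3` sRGB array (low radii at the bottom).
#' @export
colorbarImage <- function(cfg = fusionConfig(), width = 24L, height = 256L) {
  rnew <- seq(1, 0, length.out = height)
  cols <- pseudoColor(rnew)
  arr <- array(0, c(height, width, 3L))
  for (ch in 1:3) arr[, , ch] <- matrix(cols[, ch], height, width)
  arr
}
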