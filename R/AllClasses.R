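#' @import methods
NULL

## Coordinate convention used throughout the package: matrices are indexed
## [row, column]; row index increases downward (toward the posterior of the
## eye), column index increases rightward.  Boundary curves are real-valued
## functions row(column).  All indices are 1-based.

#' CorvisSequence: a stack of grayscale Scheimpflug frames
#'
#' Container for an air-puff acquisition: a list of equally sized numeric
#' matrices with intensities in \[0, 1\], the physical pixel pitch (mm per
#' pixel), and free-form metadata.
#'
#' @slot frames list of numeric matrices (rows x cols), intensities in \[0,1\].
#' @slot pixelPitch mm spanned by one pixel (isotropic).
#' @slot metadata named list (acquisition notes, generator config, ...).
#' @export
setClass("CorvisSequence",
  representation(frames = "list", pixelPitch = "numeric", metadata = "list"),
  prototype(frames = list(), pixelPitch = 0.016, metadata = list()))

setValidity("CorvisSequence", function(object) {
  if (length(object@pixelPitch) != 1L || !is.finite(object@pixelPitch) ||
      object@pixelPitch <= 0)
    return("pixelPitch must be a single positive number")
  if (length(object@frames) == 0L) return(TRUE)
  d <- dim(object@frames[[1L]])
  for (i in seq_along(object@frames)) {
    f <- object@frames[[i]]
    if (!is.matrix(f) || !is.numeric(f))
      return(sprintf("frame %d is not a numeric matrix", i))
    if (!identical(dim(f), d))
      return(sprintf("frame %d has a different shape", i))
    if (anyNA(f) || min(f) < 0 || max(f) > 1)
      return(sprintf("frame %d has intensities outside [0, 1]", i))
  }
  TRUE
})

#' GroundTruth: analytic geometry emitted by the synthetic generator
#'
#' Exact noise-free geometry of one synthetic frame: per-column boundary and
#' midline rows, the per-column signed anterior radius, central thickness,
#' and the inventory of rendered artifacts.  The sign convention for the
#' radius is positive where the anterior surface is convex toward the camera
#' (circle center at a larger row than the surface) and negative where it is
#' concave.
#'
#' @slot upperRows numeric, per-column anterior boundary row.
#' @slot lowerRows numeric, per-column posterior boundary row.
#' @slot centerRows numeric, per-column midline row.
#' @slot radiusMm numeric, per-column signed anterior radius in mm
#'   (\code{Inf} where the surface is locally flat).
#' @slot cctPx central corneal thickness in pixels (at the apex column).
#' @slot apexPositions columns of the two forward apexes flanking the central
#'   depression when the surface is concave; \code{numeric(0)} otherwise.
#' @slot apexDisplacementPx inward apex displacement (px) relative to rest.
#' @slot stage one of \code{"before"}, \code{"during"}, \code{"after"}.
#' @slot artifacts data.frame inventory of rendered artifact primitives.
#' @export
setClass("GroundTruth",
  representation(upperRows = "numeric", lowerRows = "numeric",
    centerRows = "numeric", radiusMm = "numeric", cctPx = "numeric",
    apexPositions = "numeric", apexDisplacementPx = "numeric",
    stage = "character", artifacts = "data.frame"))

setValidity("GroundTruth", function(object) {
  n <- length(object@upperRows)
  if (length(object@lowerRows) != n || length(object@centerRows) != n ||
      length(object@radiusMm) != n)
    return("per-column slots must have equal length")
  if (any(object@upperRows >= object@centerRows) ||
      any(object@centerRows >= object@lowerRows))
    return("ordering upperRows < centerRows < lowerRows violated")
  if (!object@stage %in% c("before", "during", "after"))
    return("stage must be 'before', 'during' or 'after'")
  TRUE
})

#' FilterResponses: quadrature responses of a log-Gabor bank
#'
#' Even (real) and odd (imaginary) parts and the magnitude of the complex
#' response of every (scale, orientation) filter, as 4-d arrays indexed
#' \code{[row, col, scale, orientation]}.
#'
#' @slot even,odd,amplitude numeric 4-d arrays.
#' @export
setClass("FilterResponses",
  representation(even = "array", odd = "array", amplitude = "array"))

setValidity("FilterResponses", function(object) {
  if (!identical(dim(object@even), dim(object@odd)) ||
      !identical(dim(object@even), dim(object@amplitude)))
    return("even, odd and amplitude must share dimensions")
  if (length(dim(object@even)) != 4L)
    return("responses must be [row, col, scale, orientation] arrays")
  TRUE
})

#' PhaseMaps: per-pixel phase symmetry and asymmetry
#'
#' Contrast-invariant feature maps in \[0, 1\]: symmetry responds to ridge
#' (delta-like) structure, asymmetry to step edges.
#'
#' @slot sym,asym numeric matrices in \[0, 1\].
#' @export
setClass("PhaseMaps", representation(sym = "matrix", asym = "matrix"))

setValidity("PhaseMaps", function(object) {
  if (!identical(dim(object@sym), dim(object@asym)))
    return("sym and asym must share dimensions")
  if (min(object@sym) < 0 || max(object@sym) > 1 ||
      min(object@asym) < 0 || max(object@asym) > 1)
    return("phase maps must lie in [0, 1]")
  TRUE
})

#' BinaryMask: cornea-support mask
#'
#' @slot mask logical matrix (TRUE = foreground).
#' @slot provenance character vector of the steps that produced it.
#' @export
setClass("BinaryMask",
  representation(mask = "matrix", provenance = "character"))

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  TRUE
})

#' CenterLine: corneal midline traced from the symmetry map
#'
#' Raw per-column medians of supra-threshold symmetry pixels, their
#' symmetry intensities, and the degree-5 polynomial least-squares fit
#' evaluated at every column.
#'
#' @slot rawRows numeric, per-column median row (NA where no pixel passed).
#' @slot rawIntensity numeric, symmetry value at the raw point.
#' @slot polyCoeffs numeric(6), coefficients in the scaled-column basis.
#' @slot colScale numeric(2), (center, half-range) used to scale columns.
#' @slot fittedRows numeric, polynomial evaluated at every column.
#' @slot validCols logical, columns with a raw point.
#' @export
setClass("CenterLine",
  representation(rawRows = "numeric", rawIntensity = "numeric",
    polyCoeffs = "numeric", colScale = "numeric",
    fittedRows = "numeric", validCols = "logical"))

setValidity("CenterLine", function(object) {
  if (length(object@polyCoeffs) != 6L)
    return("polyCoeffs must have length 6 (degree-5 polynomial)")
  if (anyNA(object@fittedRows) || any(!is.finite(object@fittedRows)))
    return("fittedRows must be finite everywhere")
  TRUE
})

#' SegmentationResult: full boundary segmentation of one frame
#'
#' @slot center \linkS4class{CenterLine}.
#' @slot upperRows,lowerRows numeric, fitted per-column boundary rows.
#' @slot validUpper,validLower logical, columns with a detected candidate.
#' @slot qualityFlags logical, TRUE on columns considered unreliable
#'   (outer ends of the image).
#' @export
setClass("SegmentationResult",
  representation(center = "CenterLine", upperRows = "numeric",
    lowerRows = "numeric", validUpper = "logical", validLower = "logical",
    qualityFlags = "logical"))

setValidity("SegmentationResult", function(object) {
  n <- length(object@upperRows)
  if (length(object@lowerRows) != n || length(object@validUpper) != n ||
      length(object@validLower) != n || length(object@qualityFlags) != n)
    return("per-column slots must have equal length")
  jv <- object@validUpper & object@validLower & !object@qualityFlags
  if (any(jv)) {
    cf <- object@center@fittedRows
    if (any(object@upperRows[jv] >= cf[jv]) ||
        any(cf[jv] >= object@lowerRows[jv]))
      return("ordering upper < center < lower violated on valid columns")
  }
  TRUE
})

#' CircleFit: non-iterative area-error circle fit
#'
#' Result of minimizing the sum of squared area errors
#' \eqn{\sum_i (\pi R^2 - \pi[(x_i-x_c)^2+(y_i-y_c)^2])^2} in closed form.
#'
#' @slot radiusPx fitted radius in pixels.
#' @slot centerRow,centerCol fitted center.
#' @slot residual the area-error objective at the optimum.
#' @slot nPoints number of points used.
#' @export
setClass("CircleFit",
  representation(radiusPx = "numeric", centerRow = "numeric",
    centerCol = "numeric", residual = "numeric", nPoints = "integer"))

setValidity("CircleFit", function(object) {
  if (object@radiusPx <= 0) return("radiusPx must be positive")
  if (object@residual < 0) return("residual must be nonnegative")
  if (object@nPoints < 3L) return("nPoints must be at least 3")
  TRUE
})

#' CurvatureProfile: per-column signed anterior radius
#'
#' @slot radiusMm numeric, signed radius per column (NA on invalid columns).
#' @slot validCols logical.
#' @slot halfWidth window half-size in px.
#' @slot pixelPitch mm per pixel.
#' @export
setClass("CurvatureProfile",
  representation(radiusMm = "numeric", validCols = "logical",
    halfWidth = "numeric", pixelPitch = "numeric"))

setValidity("CurvatureProfile", function(object) {
  if (length(object@radiusMm) != length(object@validCols))
    return("radiusMm and validCols must have equal length")
  if (any(!is.finite(object@radiusMm[object@validCols])))
    return("radiusMm must be finite on valid columns")
  if (object@pixelPitch <= 0) return("pixelPitch must be positive")
  TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "CorvisSequence", function(object) {
  d <- if (length(object@frames)) dim(object@frames[[1L]]) else c(0L, 0L)
  cat(sprintf("CorvisSequence: %d frame(s) of %d x %d px, pitch %.4g mm/px\n",
    length(object@frames), d[1L], d[2L], object@pixelPitch))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d columns, stage '%s', cct %.2f px, apex shift %.2f px\n",
    length(object@upperRows), object@stage, object@cctPx,
    object@apexDisplacementPx))
})

setMethod("show", "PhaseMaps", function(object) {
  cat(sprintf("PhaseMaps: %d x %d, sym in [%.3f, %.3f], asym in [%.3f, %.3f]\n",
    nrow(object@sym), ncol(object@sym), min(object@sym), max(object@sym),
    min(object@asym), max(object@asym)))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf(
    "SegmentationResult: %d columns (%d/%d valid upper/lower, %d flagged)\n",
    length(object@upperRows), sum(object@validUpper), sum(object@validLower),
    sum(object@qualityFlags)))
})

setMethod("show", "CircleFit", function(object) {
  cat(sprintf("CircleFit: R = %.3f px, center (%.2f, %.2f), J = %.3g, n = %d\n",
    object@radiusPx, object@centerRow, object@centerCol, object@residual,
    object@nPoints))
})

setMethod("show", "CurvatureProfile", function(object) {
  v <- object@radiusMm[object@validCols]
  cat(sprintf(
    "CurvatureProfile: %d columns (%d valid), radius in [%.2f, %.2f] mm\n",
    length(object@radiusMm), sum(object@validCols),
    if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})
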