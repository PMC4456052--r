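## Evaluation quantities: central corneal thickness (CCT), apex
## displacement / deformation amplitude, peak distance (PD) at highest
## concavity, and paired-series agreement (Bland-Altman limits, Pearson r).

## Central column: valid column closest to the image midline.
centralColumn <- function(valid) {
  nc <- length(valid)
  cand <- which(valid)
  if (!length(cand)) stop("no valid column")
  cand[which.min(abs(cand - nc / 2))]
}

#' Central corneal thickness from a segmentation
#'
#' Posterior-minus-anterior boundary distance at the central (apex) column
#' times the pixel pitch.
#'
#' @param seg a \linkS4class{SegmentationResult}.
#' @param pixelPitch mm per pixel.
#' @param col column to measure at; default the central jointly valid one.
#' @return CCT in mm.
#' @export
cctFromSegmentation <- function(seg, pixelPitch = 0.016, col = NULL) {
  jv <- seg@validUpper & seg@validLower
  if (is.null(col)) col <- centralColumn(jv)
  if (!jv[col]) stop("apex column is not jointly valid")
  thick <- seg@lowerRows[col] - seg@upperRows[col]
  if (thick <= 0) stop("non-positive thickness at the apex column")
  thick * pixelPitch
}

#' Per-frame apex displacement (deformation amplitude)
#'
#' Anterior boundary displacement at the central column relative to a
#' reference (rest) segmentation, in mm; positive = inward (downward).
#'
#' @param seg,refSeg \linkS4class{SegmentationResult}s of the frame and of
#'   the reference rest frame.
#' @param pixelPitch mm per pixel.
#' @return displacement in mm.
#' @export
deformationAmplitude <- function(seg, refSeg, pixelPitch = 0.016) {
  col <- centralColumn(seg@validUpper & refSeg@validUpper)
  (seg@upperRows[col] - refSeg@upperRows[col]) * pixelPitch
}

#' Frame index of highest concavity
#'
#' Argmax of the per-frame deformation amplitudes; ties broken by the
#' earliest frame.
#'
#' @param amplitudes numeric vector (one per frame, >= 3 frames).
#' @return integer frame index.
#' @export
highestConcavity <- function(amplitudes) {
  if (length(amplitudes) < 3L) stop("need at least 3 frames")
  which.max(amplitudes)
}

#' Peak distance at highest concavity
#'
#' At highest concavity the anterior surface has a central depression
#' flanked by two forward apexes (local row minima of the fitted anterior
#' boundary).  PD is the Euclidean distance between the two apex points
#' times the pixel pitch.
#'
#' @param seg \linkS4class{SegmentationResult} at the highest-concavity
#'   frame.
#' @param pixelPitch mm per pixel.
#' @param prominence minimum depth (px) of the central depression below
#'   both apexes for the concavity to count.
#' @return list with `pd` (mm), `apexCols`, `apexRows`.
#' @export
peakDistance <- function(seg, pixelPitch = 0.016, prominence = 0.5) {
  up <- seg@upperRows
  nc <- length(up)
  core <- ceiling(nc / 6):(nc - ceiling(nc / 6))
  u <- up[core]
  ## interior local row-minima of the (smooth) anterior boundary
  mins <- which(diff(sign(diff(u))) == 2) + 1L
  if (length(mins) < 2L) stop("PD undefined: no concavity detected")
  ## pick the pair with the deepest depression between them
  best <- NULL; bestDepth <- -Inf
  for (a in seq_len(length(mins) - 1L)) for (b in (a + 1L):length(mins)) {
    between <- mins[a]:mins[b]
    depth <- max(u[between]) - max(u[mins[a]], u[mins[b]])
    if (depth > bestDepth) { bestDepth <- depth; best <- c(a, b) }
  }
  leftApex <- core[mins[best[1L]]]; rightApex <- core[mins[best[2L]]]
  depCol <- core[mins[best[1L]] - 1L +
    which.max(u[mins[best[1L]]:mins[best[2L]]])]
  if (up[depCol] - up[leftApex] < prominence ||
      up[depCol] - up[rightApex] < prominence)
    stop("PD undefined: no concavity detected")
  dpx <- sqrt((up[rightApex] - up[leftApex])^2 + (rightApex - leftApex)^2)
  list(pd = dpx * pixelPitch, apexCols = c(leftApex, rightApex),
    apexRows = c(up[leftApex], up[rightApex]), depressionCol = depCol)
}

#' Bland-Altman agreement statistics
#'
#' Differences `d = a - b`, their mean, the limits `mean(d) +/- 2 sd(d)`
#' (sample SD), and the fraction of points outside the limits.
#'
#' @param a,b paired numeric series of equal length >= 2.
#' @return list with `meanDiff`, `lower`, `upper`, `fracOutside`, `diffs`.
#' @export
blandAltman <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- a - b
  m <- mean(d); s <- stats::sd(d)
  lims <- c(m - 2 * s, m + 2 * s)
  list(meanDiff = m, lower = lims[1L], upper = lims[2L],
    fracOutside = mean(d < lims[1L] | d > lims[2L]), diffs = d)
}

#' Pearson product-moment correlation
#'
#' @param a,b numeric series of equal length >= 3 with nonzero variance.
#' @return correlation coefficient.
#' @export
pearsonR <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ")
  if (length(a) < 3L) stop("need at least 3 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("zero variance")
  stats::cor(a, b)
}

#' Per-sequence metrics table
#'
#' @param segs list of \linkS4class{SegmentationResult}, one per frame.
#' @param pixelPitch mm per pixel.
#' @param refFrame index of the reference rest frame (default 1).
#' @param stageThresholdMm displacement (mm) separating "during" from
#'   "before"/"after".
#' @return data.frame with frame, stage, cctMm, amplitudeMm, pdMm.
#' @export
sequenceMetrics <- function(segs, pixelPitch = 0.016, refFrame = 1L,
    stageThresholdMm = 0.15) {
  amp <- vapply(segs, deformationAmplitude, numeric(1L),
    refSeg = segs[[refFrame]], pixelPitch = pixelPitch)
  hc <- if (length(amp) >= 3L) highestConcavity(amp) else which.max(amp)
  stage <- ifelse(amp > stageThresholdMm, "during",
    ifelse(seq_along(segs) <= hc, "before", "after"))
  cct <- vapply(segs, function(s)
    tryCatch(cctFromSegmentation(s, pixelPitch), error = function(e) NA_real_),
    numeric(1L))
  pd <- rep(NA_real_, length(segs))
  pdRes <- tryCatch(peakDistance(segs[[hc]], pixelPitch),
    error = function(e) NULL)
  if (!is.null(pdRes)) pd[hc] <- pdRes$pd
  data.frame(frame = seq_along(segs), stage = stage, cctMm = cct,
    amplitudeMm = amp, pdMm = pd)
}
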