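## Boundary segmentation: the corneal midline is traced as the per-column
## median of supra-threshold phase-symmetry pixels inside the cornea mask
## and smoothed with a degree-5 polynomial; the anterior/posterior
## boundaries are the asymmetry peaks nearest the midline on either side,
## smoothed the same way.

## Lower median: element at position ceiling(n/2) of the sorted values, so
## the midline point stays on an actual pixel row for even-sized sets.
lowerMedian <- function(x) sort(x)[ceiling(length(x) / 2)]

## Degree-5 polynomial least-squares fit of rows ~ columns, on columns
## scaled to [-1, 1] for conditioning.  Returns coefficients, scaling and
## the fit evaluated at every column of `allCols`.
polyFit5 <- function(cols, rows, weights = NULL, allCols) {
  ok <- is.finite(rows)
  cols <- cols[ok]; rows <- rows[ok]
  if (!is.null(weights)) weights <- weights[ok]
  if (length(unique(cols)) < 6L)
    stop("insufficient support for degree-5 fit (need >= 6 valid columns)")
  ctr <- mean(range(allCols)); half <- diff(range(allCols)) / 2
  x <- (cols - ctr) / half
  X <- outer(x, 0:5, `^`)
  fit <- stats::lm.wfit(X, rows,
    w = if (is.null(weights)) rep(1, length(rows)) else weights)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  xa <- (allCols - ctr) / half
  list(coeffs = beta, colScale = c(ctr, half),
    fitted = drop(outer(xa, 0:5, `^`) %*% beta))
}

#' Trace the corneal midline from the phase-symmetry map
#'
#' For each column `j`, the rows of mask-interior pixels whose symmetry
#' exceeds `tau` form the set `L_j`; the raw midline point is
#' `(median(L_j), j)` with the symmetry value at that point recorded as its
#' intensity.  A degree-5 polynomial least-squares fit over the valid
#' columns (optionally weighted by the recorded intensity) yields the
#' midline at every column.
#'
#' @param sym phase-symmetry matrix in \[0, 1\].
#' @param mask a \linkS4class{BinaryMask} restricting the search to the
#'   cornea.
#' @param tau symmetry threshold (default 0.1).
#' @param weighted use the raw-point intensities as least-squares weights
#'   (default TRUE); FALSE gives the unweighted fit.
#' @param support optional logical vector of columns admitted to the fit
#'   (raw points are still recorded everywhere); used to keep the
#'   unreliable image ends out of the polynomial.
#' @return a \linkS4class{CenterLine}.
#' @export
centerLine <- function(sym, mask, tau = 0.1, weighted = TRUE,
    support = NULL) {
  stopifnot(is(mask, "BinaryMask"))
  if (!identical(dim(sym), dim(mask@mask)))
    stop("sym and mask shapes differ")
  nc <- ncol(sym)
  rawRows <- rawInt <- rep(NA_real_, nc)
  for (j in seq_len(nc)) {
    L <- which(sym[, j] > tau & mask@mask[, j])
    if (length(L)) {
      r <- lowerMedian(L)
      rawRows[j] <- r
      rawInt[j] <- sym[r, j]
    }
  }
  valid <- !is.na(rawRows)
  fitUse <- valid & (if (is.null(support)) TRUE else support)
  if (sum(fitUse) < 6L)
    stop("insufficient support for degree-5 fit (need >= 6 valid columns)")
  pf <- polyFit5(which(fitUse), rawRows[fitUse],
    weights = if (weighted) rawInt[fitUse] else NULL,
    allCols = seq_len(nc))
  new("CenterLine", rawRows = rawRows, rawIntensity = rawInt,
    polyCoeffs = pf$coeffs, colScale = pf$colScale,
    fittedRows = pf$fitted, validCols = valid)
}

#' Boundary candidates from the phase-asymmetry map
#'
#' Per column, candidate rows are taken from the asymmetry map above
#' threshold `tau`, restricted to a window of `searchFactor` times the
#' expected band thickness around the fitted midline.  The candidate with
#' the largest row strictly above the midline becomes the upper (anterior)
#' point; the smallest row strictly below becomes the lower (posterior)
#' point.  With `mode = "peak"` (default) only column-wise local maxima of
#' the asymmetry qualify, and the selected peak is refined to sub-pixel
#' position by parabolic interpolation; `mode = "any"` admits every
#' supra-threshold pixel.
#'
#' @param asym phase-asymmetry matrix.
#' @param center a \linkS4class{CenterLine}.
#' @param tau asymmetry threshold (default 0.3; the 0.1 convention belongs
#'   to the symmetry map, and the band interior carries weak ringing
#'   responses around 0.2 that must not qualify as edges).
#' @param bandThickness expected band thickness in px (sets the search
#'   window); estimate it from the cornea mask.
#' @param searchFactor half-window as a fraction of `bandThickness`.
#' @param mode `"peak"` or `"any"`.
#' @param refine sub-pixel parabolic refinement (peak mode only).
#' @return list with numeric `upper`, `lower` (NA where no candidate) and
#'   logical `validUpper`, `validLower`.
#' @export
boundaryPoints <- function(asym, center, tau = 0.3, bandThickness,
    searchFactor = 0.75, mode = c("peak", "any"), refine = TRUE) {
  mode <- match.arg(mode)
  nc <- ncol(asym); nr <- nrow(asym)
  ctr <- center@fittedRows
  halfWin <- searchFactor * bandThickness
  upper <- lower <- rep(NA_real_, nc)
  for (j in seq_len(nc)) {
    col <- asym[, j]
    if (mode == "peak") {
      dd <- diff(sign(diff(col)))
      cand <- which(dd == -2) + 1L
      cand <- cand[col[cand] > tau]
    } else {
      cand <- which(col > tau)
    }
    upC <- cand[cand < ctr[j] & cand >= ctr[j] - halfWin]
    loC <- cand[cand > ctr[j] & cand <= ctr[j] + halfWin]
    if (length(upC)) {
      p <- max(upC)
      upper[j] <- if (mode == "peak" && refine) refinePeak(col, p) else p
    }
    if (length(loC)) {
      p <- min(loC)
      lower[j] <- if (mode == "peak" && refine) refinePeak(col, p) else p
    }
  }
  list(upper = upper, lower = lower,
    validUpper = !is.na(upper), validLower = !is.na(lower))
}

## Three-point parabolic sub-pixel refinement of a local maximum at p.
refinePeak <- function(col, p) {
  if (p <= 1L || p >= length(col)) return(as.numeric(p))
  denom <- col[p - 1L] - 2 * col[p] + col[p + 1L]
  if (denom >= 0) return(as.numeric(p))
  p + (col[p - 1L] - col[p + 1L]) / (2 * denom)
}

#' Fit a smooth per-column boundary through candidate points
#'
#' Degree-5 polynomial least-squares fit over the valid columns, evaluated
#' at every column.
#'
#' @param rows numeric candidate rows (NA = invalid column).
#' @param cols columns of the candidates (default `seq_along(rows)`).
#' @param allCols columns at which to evaluate the fit.
#' @param weights optional least-squares weights.
#' @return numeric fitted rows over `allCols`.
#' @export
fitBoundary <- function(rows, cols = seq_along(rows),
    allCols = seq_along(rows), weights = NULL) {
  polyFit5(cols, rows, weights = weights, allCols = allCols)$fitted
}

#' Smoothing-spline boundary fit with outlier rejection
#'
#' Cubic smoothing spline with a fixed equivalent degrees of freedom,
#' refitted once after discarding candidates whose residual exceeds
#' 3 x the median absolute residual (artifact-touched columns).  A global
#' quintic cannot represent the localized concavity the air puff
#' imprints on the anterior surface at highest deformation, so this is
#' the default boundary model of [segmentCornea()].
#'
#' @param rows candidate rows (NA = invalid column).
#' @param cols candidate columns.
#' @param allCols columns at which to evaluate the fit.
#' @param df equivalent degrees of freedom of the spline.
#' @return numeric fitted rows over `allCols` (linear extrapolation
#'   outside the candidate range).
#' @export
fitBoundarySpline <- function(rows, cols = seq_along(rows),
    allCols = seq_along(rows), df = 15) {
  ok <- is.finite(rows)
  x <- cols[ok]; y <- rows[ok]
  if (length(x) < df + 2L)
    stop("insufficient support for the spline fit")
  ss <- stats::smooth.spline(x, y, df = df)
  res <- y - stats::predict(ss, x)$y
  keep <- abs(res) <= 3 * max(stats::mad(res), 0.1)
  if (sum(keep) >= df + 2L && any(!keep))
    ss <- stats::smooth.spline(x[keep], y[keep], df = df)
  stats::predict(ss, allCols)$y
}

#' Segment the corneal boundaries of one frame
#'
#' Full per-frame segmentation: artifact removal ([corneaMask()]),
#' phase maps on the masked frame ([phaseMaps()]), midline tracing
#' ([centerLine()]), boundary candidate detection ([boundaryPoints()]) and
#' polynomial smoothing ([fitBoundary()]).  The outer sixth of the columns
#' at each end is flagged as unreliable (the phase responses fade there),
#' so quantitative use should stick to the central two thirds.
#'
#' @param frame numeric matrix in \[0, 1\].
#' @param config a [pipelineConfig()]; individual blocks control each step.
#' @return a \linkS4class{SegmentationResult}.
#' @export
segmentCornea <- function(frame, config = pipelineConfig()) {
  pc <- config$preprocess
  mask <- corneaMask(frame, se = pc$se, ratio = pc$ratio)
  masked <- applyMask(frame, growMask(mask, margin = pc$maskGrow))
  fb <- do.call(filterBankConfig, config$phase)
  pm <- phaseMaps(masked, fb)
  sc <- config$segmentation
  nc <- ncol(frame)
  flags <- seq_len(nc) <= ceiling(nc / 6) | seq_len(nc) > nc - ceiling(nc / 6)
  ctr <- centerLine(pm@sym, mask, tau = sc$tauSym, weighted = sc$weighted,
    support = !flags)
  colMass <- colSums(mask@mask)
  thickness <- stats::median(colMass[colMass > 0])
  bp <- boundaryPoints(pm@asym, ctr, tau = sc$tauAsym,
    bandThickness = thickness, searchFactor = sc$searchFactor,
    mode = sc$candidateMode, refine = sc$refine)
  fitOne <- function(rows) {
    rows[flags] <- NA_real_  # ends are unreliable; extrapolate instead
    if (identical(sc$boundaryModel, "poly5"))
      fitBoundary(rows, allCols = seq_len(nc))
    else
      fitBoundarySpline(rows, allCols = seq_len(nc), df = sc$boundaryDf)
  }
  upFit <- fitOne(bp$upper)
  loFit <- fitOne(bp$lower)
  new("SegmentationResult", center = ctr, upperRows = upFit,
    lowerRows = loFit, validUpper = bp$validUpper,
    validLower = bp$validLower, qualityFlags = flags)
}
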