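## Per-column signed radius of the anterior boundary via the non-iterative
## area-error circle fit: minimize
##   J = sum_i (pi R^2 - pi[(x_i-x_c)^2 + (y_i-y_c)^2])^2.
## Substituting B = R^2 - x_c^2 - y_c^2 makes the bracket linear in
## (B, x_c, y_c), so the minimizer solves a 3x3 normal system in closed
## form -- no iteration, no initial guess.

#' Area-error circle fit
#'
#' @param rows,cols coordinates of at least 3 non-collinear points.
#' @return a \linkS4class{CircleFit}.
#' @examples
#' th <- seq(0, pi, length.out = 10)
#' circleFitArea(100 + 50 * sin(th), 100 + 50 * cos(th))
#' @export
circleFitArea <- function(rows, cols) {
  n <- length(rows)
  if (length(cols) != n) stop("rows and cols must have equal length")
  if (n < 3L) stop("need at least 3 points")
  ## center the coordinates first: the solution is translation-equivariant
  ## and the normal system is far better conditioned about the centroid
  mr <- mean(rows); mc <- mean(cols)
  x <- rows - mr; y <- cols - mc
  ev <- eigen(stats::cov(cbind(x, y)), symmetric = TRUE,
    only.values = TRUE)$values
  if (ev[2L] <= 1e-10 * ev[1L])
    stop("degenerate arc: points are (near-)collinear")
  z <- x^2 + y^2
  X <- cbind(1, 2 * x, 2 * y)
  sol <- solve(crossprod(X), crossprod(X, z))
  B <- sol[1L]; xc0 <- sol[2L]; yc0 <- sol[3L]
  R2 <- B + xc0^2 + yc0^2
  if (R2 <= 0) stop("no real radius")
  R <- sqrt(R2)
  xc <- xc0 + mr; yc <- yc0 + mc
  resid <- sum((pi * R2 - pi * ((rows - xc)^2 + (cols - yc)^2))^2)
  new("CircleFit", radiusPx = R, centerRow = xc, centerCol = yc,
    residual = resid, nPoints = as.integer(n))
}

#' Sliding-window signed curvature profile of a boundary
#'
#' For every column with a full window of `halfWidth` boundary samples on
#' each side (55 points at the default 27), the window is fitted with
#' [circleFitArea()]; the signed radius is
#' `+radiusPx * pixelPitch` when the fitted center lies below the boundary
#' at the target column (anterior surface convex toward the camera) and
#' negative otherwise.  Columns without a full valid window, or whose
#' window is degenerate (straight boundary), are flagged invalid.
#'
#' @param boundaryRows numeric per-column boundary rows (typically the
#'   fitted anterior boundary of a \linkS4class{SegmentationResult}).
#' @param halfWidth window half-size in px (default 27).
#' @param pixelPitch mm per pixel (default 0.016).
#' @param validCols logical, columns usable as window samples (default all
#'   finite entries of `boundaryRows`).
#' @return a \linkS4class{CurvatureProfile}.
#' @export
curvatureProfile <- function(boundaryRows, halfWidth = 27L,
    pixelPitch = 0.016, validCols = NULL) {
  nc <- length(boundaryRows)
  if (is.null(validCols)) validCols <- is.finite(boundaryRows)
  if (sum(validCols) < 2L * halfWidth + 1L)
    stop("boundary must be valid over at least 2*halfWidth + 1 columns")
  radius <- rep(NA_real_, nc)
  ok <- rep(FALSE, nc)
  for (j in seq_len(nc)) {
    win <- (j - halfWidth):(j + halfWidth)
    if (win[1L] < 1L || win[length(win)] > nc) next
    if (!all(validCols[win])) next
    fit <- tryCatch(circleFitArea(boundaryRows[win], win),
      error = function(e) NULL)
    if (is.null(fit)) next
    sgn <- if (fit@centerRow > boundaryRows[j]) 1 else -1
    radius[j] <- sgn * fit@radiusPx * pixelPitch
    ok[j] <- TRUE
  }
  new("CurvatureProfile", radiusMm = radius, validCols = ok,
    halfWidth = as.numeric(halfWidth), pixelPitch = pixelPitch)
}
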