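## Artifact removal: global binarization, morphological closing with a
## horizontal 10 x 60 rectangular structuring element (bridging the gaps
## that uneven illumination cuts into the band), and 8-connected
## component-area filtering that keeps every component at least 1/3 the
## size of the largest one.  Eyelashes and tears are far smaller than the
## cornea, so they are removed; only artifacts touching the band survive
## (and are handled downstream by the candidate search).

#' Binarize a frame with a global automatic threshold
#'
#' @param frame numeric matrix in \[0, 1\].
#' @param method only `"otsu"` (Otsu's threshold on the 256-bin intensity
#'   histogram).
#' @return a \linkS4class{BinaryMask}.
#' @export
binarizeFrame <- function(frame, method = "otsu") {
  method <- match.arg(method, "otsu")
  if (min(frame) < 0 || max(frame) > 1) stop("frame must lie in [0, 1]")
  if (diff(range(frame)) < 1e-12) stop("empty frame")
  thr <- EBImage::otsu(EBImage::Image(frame), range = c(0, 1))
  m <- frame > thr
  if (!any(m)) stop("empty frame")
  new("BinaryMask", mask = m, provenance = sprintf("otsu(%.4f)", thr))
}

#' Bridge illumination gaps by morphological closing
#'
#' Binary closing with a rectangular structuring element (default
#' 10 rows x 60 columns, long axis horizontal to match the near-horizontal
#' corneal band).  The mask is zero-padded by the element size before
#' closing so the operation is extensive everywhere (output is a superset
#' of the input foreground, including at the image border).
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param se integer(2), structuring element size (rows, cols).
#' @return closed \linkS4class{BinaryMask}.
#' @export
closeGaps <- function(mask, se = c(10L, 60L)) {
  stopifnot(is(mask, "BinaryMask"))
  m <- mask@mask
  pr <- as.integer(se[1L]); pc <- as.integer(se[2L])
  big <- matrix(FALSE, nrow(m) + 2L * pr, ncol(m) + 2L * pc)
  big[pr + seq_len(nrow(m)), pc + seq_len(ncol(m))] <- m
  closed <- rectClose(big, pr, pc)
  out <- closed[pr + seq_len(nrow(m)), pc + seq_len(ncol(m))]
  new("BinaryMask", mask = out,
    provenance = c(mask@provenance, sprintf("closing(%dx%d)", pr, pc)))
}

## Shift a logical matrix by (dr, dc), filling with FALSE.
shiftMat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1L, 1L - dr):min(nr, nr - dr)
  cs <- max(1L, 1L - dc):min(nc, nc - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

## Separable rectangular binary closing (exact, shift-free): dilation
## y[i] = OR_{u in SE} x[i - u], erosion z[i] = AND_{u in SE} y[i + u],
## with SE offsets -a..b per axis.  This pairing makes the closing
## extensive and idempotent regardless of even/odd element sizes.
rectClose <- function(m, kr, kc) {
  ar <- (kr - 1L) %/% 2L; br <- kr - 1L - ar
  ac <- (kc - 1L) %/% 2L; bc <- kc - 1L - ac
  lineOp <- function(x, shifts, dim, combine) {
    acc <- NULL
    for (s in shifts) {
      sh <- if (dim == 1L) shiftMat(x, s, 0L) else shiftMat(x, 0L, s)
      acc <- if (is.null(acc)) sh else combine(acc, sh)
    }
    acc
  }
  dil <- lineOp(m, -br:ar, 1L, `|`)
  dil <- lineOp(dil, -bc:ac, 2L, `|`)
  er <- lineOp(dil, -ar:br, 1L, `&`)
  lineOp(er, -ac:bc, 2L, `&`)
}

## 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that
## touch diagonally are merged through a union-find pass over the label
## adjacency graph.
label8 <- function(m) {
  lab <- EBImage::bwlabel(EBImage::Image(m * 1))
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  nlab <- max(lab)
  if (nlab < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1L, -1L])),
    cbind(as.vector(lab[-1L, -nc]), as.vector(lab[-nr, -1L])))
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
    pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1L]); b <- find(pairs[k, 2L])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nlab), find, integer(1L))
  root <- match(root, sort(unique(root)))
  lab[lab > 0L] <- root[lab[lab > 0L]]
  lab
}

#' Keep only large connected components
#'
#' Labels 8-connected foreground components and retains every component
#' whose area is at least `ratio` times the largest component's area.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param ratio area threshold as a fraction of the biggest component
#'   (default 1/3).
#' @return filtered \linkS4class{BinaryMask}.
#' @export
keepLarge <- function(mask, ratio = 1 / 3) {
  stopifnot(is(mask, "BinaryMask"))
  m <- mask@mask
  if (!any(m)) stop("mask has no foreground component")
  lab <- label8(m)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= ratio * max(areas))
  out <- matrix(lab %in% keep & lab > 0L, nrow(m), ncol(m))
  new("BinaryMask", mask = out,
    provenance = c(mask@provenance, sprintf("keepLarge(%.3f)", ratio)))
}

#' Apply a binary mask to a frame
#'
#' @param frame numeric matrix.
#' @param mask a \linkS4class{BinaryMask} of the same shape.
#' @return masked frame (background zeroed).
#' @export
applyMask <- function(frame, mask) {
  stopifnot(is(mask, "BinaryMask"))
  if (!identical(dim(frame), dim(mask@mask)))
    stop("frame and mask shapes differ")
  frame * mask@mask
}

#' Cornea-only mask of a frame
#'
#' Composes [binarizeFrame()], [closeGaps()] and [keepLarge()].
#'
#' @param frame numeric matrix in \[0, 1\].
#' @param se structuring element size for [closeGaps()].
#' @param ratio area ratio for [keepLarge()].
#' @return a \linkS4class{BinaryMask}.
#' @export
corneaMask <- function(frame, se = c(10L, 60L), ratio = 1 / 3) {
  keepLarge(closeGaps(binarizeFrame(frame), se = se), ratio = ratio)
}

#' Dilate a mask by a square structuring element
#'
#' Used before [applyMask()] in the segmentation pipeline so the diffuse
#' intensity tails of the corneal band survive the multiplication: the
#' binarized component stops at the threshold crossing, a couple of pixels
#' inside the band, and a hard cut there would displace the phase-asymmetry
#' edge response.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param margin square element half-size in px (side `2*margin+1`).
#' @return dilated \linkS4class{BinaryMask}.
#' @export
growMask <- function(mask, margin = 4L) {
  stopifnot(is(mask, "BinaryMask"))
  if (margin <= 0L) return(mask)
  kern <- matrix(1L, 2L * margin + 1L, 2L * margin + 1L)
  out <- EBImage::dilate(mask@mask * 1, kern) > 0
  new("BinaryMask", mask = out,
    provenance = c(mask@provenance, sprintf("grow(%d)", margin)))
}
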