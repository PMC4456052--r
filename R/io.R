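## File I/O: multi-page TIFF stacks or PNG/TIFF directories in, CSV and
## PNG exports out.  Frames are normalized to [0, 1] by the file bit depth
## (never per-frame min-max, which would break palette comparability
## across frames).

#' Read a frame sequence
#'
#' Accepts a multi-page TIFF stack or a directory of single-frame
#' PNG/TIFF images (frames in lexicographic filename order).  All frames
#' must share one shape.  AVI containers are not supported; extract frames
#' to TIFF/PNG first.
#'
#' @param path TIFF file or directory.
#' @param pixelPitch mm per pixel to attach to the sequence.
#' @return a \linkS4class{CorvisSequence}.
#' @export
readSequence <- function(path, pixelPitch = 0.016) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
      ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop(sprintf("no PNG/TIFF frames in %s", path))
    frames <- lapply(files, readFrameFile)
  } else if (file.exists(path)) {
    if (grepl("\\.avi$", path, ignore.case = TRUE))
      stop("AVI input is not supported; extract frames to TIFF/PNG first")
    if (!grepl("\\.(tif|tiff)$", path, ignore.case = TRUE))
      stop(sprintf("unreadable input: %s (need TIFF stack or directory)", path))
    pages <- tiff::readTIFF(path, all = TRUE)
    if (is.matrix(pages)) pages <- list(pages)
    frames <- lapply(pages, asGrayMatrix)
  } else stop(sprintf("input not found: %s", path))
  d <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1L))))
    stop("frames have mixed shapes")
  new("CorvisSequence", frames = frames, pixelPitch = pixelPitch,
    metadata = list(source = path))
}

readFrameFile <- function(f) {
  img <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
    else tiff::readTIFF(f)
  asGrayMatrix(img)
}

## collapse RGB(A) planes to gray; readTIFF/readPNG already scale by the
## dtype maximum
asGrayMatrix <- function(img) {
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  pmin(pmax(img, 0), 1)
}

#' Write a frame sequence as a TIFF stack
#'
#' @param sequence a \linkS4class{CorvisSequence}.
#' @param path output `.tif` path.
#' @param bitDepth 8 or 16.
#' @return the path, invisibly.
#' @export
writeSequence <- function(sequence, path, bitDepth = 16L) {
  stopifnot(is(sequence, "CorvisSequence"))
  if (!bitDepth %in% c(8L, 16L)) stop("bitDepth must be 8 or 16")
  tiff::writeTIFF(frames(sequence), path, bits.per.sample = bitDepth)
  invisible(path)
}

#' Export ground truth as CSV (+ JSON sidecar)
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param csvPath output CSV (column, upper_row, lower_row, radius_mm).
#' @param jsonPath optional JSON sidecar with the scalar fields.
#' @return `csvPath`, invisibly.
#' @export
writeGroundTruth <- function(truth, csvPath, jsonPath = NULL) {
  df <- data.frame(column = seq_along(truth@upperRows),
    upper_row = truth@upperRows, lower_row = truth@lowerRows,
    radius_mm = truth@radiusMm)
  utils::write.csv(df, csvPath, row.names = FALSE)
  if (!is.null(jsonPath)) {
    jsonlite::write_json(list(cct_px = truth@cctPx,
      apex_positions = truth@apexPositions,
      apex_displacement_px = truth@apexDisplacementPx,
      stage = truth@stage), jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(csvPath)
}

#' Export a segmentation as CSV
#'
#' @param seg a \linkS4class{SegmentationResult}.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeSegmentation <- function(seg, path) {
  df <- data.frame(column = seq_along(seg@upperRows),
    upper_row = seg@upperRows, center_row = seg@center@fittedRows,
    lower_row = seg@lowerRows,
    valid_upper = seg@validUpper, valid_lower = seg@validLower,
    flagged = seg@qualityFlags)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a curvature profile as CSV
#'
#' @param prof a \linkS4class{CurvatureProfile}.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeProfile <- function(prof, path) {
  df <- data.frame(column = seq_along(prof@radiusMm),
    radius_mm = prof@radiusMm, valid = prof@validCols)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Segmentation overlay image
#'
#' RGB overlay in the usual convention: upper boundary green, lower
#' boundary yellow, center line red.
#'
#' @param frame numeric matrix in \[0, 1\].
#' @param seg a \linkS4class{SegmentationResult}.
#' @param path optional PNG output path.
#' @return the RGB array, invisibly.
#' @export
overlayImage <- function(frame, seg, path = NULL) {
  nr <- nrow(frame); nc <- ncol(frame)
  arr <- array(rep(frame, 3L), c(nr, nc, 3L))
  paint <- function(arr, rows, cols, rgb) {
    ok <- rows >= 1 & rows <= nr
    idx <- cbind(rows[ok], cols[ok])
    for (ch in 1:3) arr[cbind(idx, ch)] <- rgb[ch]
    arr
  }
  cols <- seq_len(nc)
  arr <- paint(arr, round(seg@upperRows), cols, c(0, 1, 0))
  arr <- paint(arr, round(seg@lowerRows), cols, c(1, 1, 0))
  arr <- paint(arr, round(seg@center@fittedRows), cols, c(1, 0, 0))
  if (!is.null(path)) png::writePNG(arr, path)
  invisible(arr)
}
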