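## End-to-end driver: per frame, segment -> curvature profile -> normalize
## -> render; per sequence, the metrics table, CSV exports, rendered PNG
## frames and a machine-readable run manifest.

#' Run the full topography pipeline on a sequence
#'
#' Applies [segmentCornea()] and [curvatureProfile()] to every frame,
#' assembles the metrics table ([sequenceMetrics()]), renders the fused
#' topography frames ([renderVideo()]) and writes everything (per-frame
#' CSVs, metrics CSV, PNG frames, colorbar, JSON manifest) under `outDir`.
#' Per-frame failures are logged and flagged; the run aborts only if more
#' than half the frames fail.
#'
#' @param input a \linkS4class{CorvisSequence}, or a path accepted by
#'   [readSequence()].
#' @param config a [pipelineConfig()].
#' @param outDir output directory; `NULL` returns results without writing.
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @param render render fused topography frames (set `FALSE` to skip the
#'   visualization stage).
#' @return list with `segs`, `profs`, `metrics`, `failedFrames`,
#'   `rendered` (if `render`), `manifest`.
#' @export
runPipeline <- function(input, config = pipelineConfig(), outDir = NULL,
    seed = 1L, render = TRUE) {
  sequence <- if (is(input, "CorvisSequence")) input
    else readSequence(input, pixelPitch = config$io$pixelPitch)
  n <- nFrames(sequence)
  if (n == 0L) stop("empty sequence")
  segs <- vector("list", n)
  profs <- vector("list", n)
  failed <- logical(n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      seg <- segmentCornea(frames(sequence)[[i]], config)
      prof <- curvatureProfile(upperRows(seg),
        halfWidth = config$curvature$halfWidth,
        pixelPitch = config$curvature$pixelPitch,
        validCols = seg@validUpper)
      list(seg = seg, prof = prof)
    }, error = function(e) {
      message(sprintf("frame %d failed: %s", i, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) failed[i] <- TRUE
    else { segs[[i]] <- res$seg; profs[[i]] <- res$prof }
  }
  if (mean(failed) > 0.5)
    stop(sprintf("pipeline aborted: %d of %d frames failed", sum(failed), n))
  okIdx <- which(!failed)
  refPos <- which(okIdx >= config$metrics$refFrame)
  metrics <- sequenceMetrics(segs[okIdx],
    pixelPitch = config$curvature$pixelPitch,
    refFrame = if (length(refPos)) min(refPos) else 1L,
    stageThresholdMm = config$metrics$stageThresholdMm)
  metrics$frame <- okIdx
  rendered <- NULL
  if (render) {
    fcfg <- fusionFromPipeline(config)
    okSeq <- new("CorvisSequence", frames = frames(sequence)[okIdx],
      pixelPitch = pixelPitch(sequence))
    results <- lapply(okIdx, function(i)
      list(seg = segs[[i]], prof = profs[[i]]))
    rendered <- renderVideo(okSeq, results, fcfg,
      outDir = if (is.null(outDir)) NULL else file.path(outDir, "frames"))
  }
  manifest <- list(
    package = "corvistopo",
    version = as.character(utils::packageVersion("corvistopo")),
    rversion = as.character(getRversion()),
    seed = seed,
    nFrames = n, failedFrames = which(failed),
    configHash = configHash(config))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(outDir, "metrics.csv"),
      row.names = FALSE)
    segDir <- file.path(outDir, "segmentation")
    dir.create(segDir, showWarnings = FALSE)
    for (i in okIdx) {
      writeSegmentation(segs[[i]],
        file.path(segDir, sprintf("seg_%04d.csv", i)))
      writeProfile(profs[[i]],
        file.path(segDir, sprintf("curvature_%04d.csv", i)))
    }
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, null = "list")
  }
  list(segs = segs, profs = profs, metrics = metrics,
    failedFrames = which(failed), rendered = rendered, manifest = manifest)
}

## MD5 of the canonical JSON serialization of the config
configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
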