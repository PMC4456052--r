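## Accessor generics and methods.  Slot access from user code should go
## through these.

#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @export
setGeneric("symMap", function(x) standardGeneric("symMap"))
#' @export
setGeneric("asymMap", function(x) standardGeneric("asymMap"))
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))
#' @export
setGeneric("upperRows", function(x) standardGeneric("upperRows"))
#' @export
setGeneric("lowerRows", function(x) standardGeneric("lowerRows"))
#' @export
setGeneric("centerRows", function(x) standardGeneric("centerRows"))
#' @export
setGeneric("radiusMm", function(x) standardGeneric("radiusMm"))
#' @export
setGeneric("radiusPx", function(x) standardGeneric("radiusPx"))
#' @export
setGeneric("validCols", function(x) standardGeneric("validCols"))
#' @export
setGeneric("qualityFlags", function(x) standardGeneric("qualityFlags"))
#' @export
setGeneric("stageLabel", function(x) standardGeneric("stageLabel"))

#' Accessors for corvistopo containers
#'
#' @param x a corvistopo S4 object.
#' @name accessors
#' @aliases frames pixelPitch nFrames symMap asymMap maskMatrix upperRows
#'   lowerRows centerRows radiusMm radiusPx validCols qualityFlags stageLabel
NULL

setMethod("frames", "CorvisSequence", function(x) x@frames)
setMethod("pixelPitch", "CorvisSequence", function(x) x@pixelPitch)
setMethod("nFrames", "CorvisSequence", function(x) length(x@frames))

setMethod("symMap", "PhaseMaps", function(x) x@sym)
setMethod("asymMap", "PhaseMaps", function(x) x@asym)

setMethod("maskMatrix", "BinaryMask", function(x) x@mask)

setMethod("upperRows", "GroundTruth", function(x) x@upperRows)
setMethod("lowerRows", "GroundTruth", function(x) x@lowerRows)
setMethod("centerRows", "GroundTruth", function(x) x@centerRows)
setMethod("radiusMm", "GroundTruth", function(x) x@radiusMm)
setMethod("stageLabel", "GroundTruth", function(x) x@stage)

setMethod("upperRows", "SegmentationResult", function(x) x@upperRows)
setMethod("lowerRows", "SegmentationResult", function(x) x@lowerRows)
setMethod("centerRows", "SegmentationResult",
  function(x) x@center@fittedRows)
setMethod("qualityFlags", "SegmentationResult", function(x) x@qualityFlags)

setMethod("radiusMm", "CurvatureProfile", function(x) x@radiusMm)
setMethod("validCols", "CurvatureProfile", function(x) x@validCols)
setMethod("pixelPitch", "CurvatureProfile", function(x) x@pixelPitch)

setMethod("radiusPx", "CircleFit", function(x) x@radiusPx)
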