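#' @rdname BoldSeries-class
#' @param x an object.
#' @export
setGeneric("boldData", function(x) standardGeneric("boldData"))

#' @rdname BoldSeries-class
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))

#' @rdname BoldSeries-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname BoldSeries-class
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))

#' @rdname BoldSeries-class
#' @export
setGeneric("voxelDims", function(x) standardGeneric("voxelDims"))

#' Discard initial frames
#'
#' Removes the first `nDiscard` frames of a [BoldSeries-class] or
#' [MotionTrace-class] (dummy scans acquired before magnetization
#' equilibrium). At TR 0.4 s the conventional 25 frames correspond to the
#' first 10 s of the scan.
#'
#' @param x a [BoldSeries-class] or [MotionTrace-class].
#' @param nDiscard non-negative integer, strictly less than the number of
#'   frames.
#' @return An object of the same class with `nFrames - nDiscard` frames;
#'   the remaining frames are unchanged.
#' @examples
#' s <- BoldSeries(array(rnorm(2 * 2 * 2 * 20), c(2, 2, 2, 20)),
#'                 voxelSize = c(3, 3, 4), tr = 0.4)
#' nFrames(discardInitial(s, 5))
#' @export
setGeneric("discardInitial", function(x, nDiscard) standardGeneric("discardInitial"))

#' @rdname LagMap-class
#' @param x an object.
#' @export
setGeneric("lagValues", function(x) standardGeneric("lagValues"))

#' @rdname LagMap-class
#' @export
setGeneric("peakCorrelation", function(x) standardGeneric("peakCorrelation"))

#' @rdname LagMap-class
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname NullCalibration-class
#' @param x an object.
#' @export
setGeneric("rThreshold", function(x) standardGeneric("rThreshold"))

#' @rdname DelineationResult-class
#' @param x an object.
#' @export
setGeneric("lesionMask", function(x) standardGeneric("lesionMask"))

#' @rdname DelineationResult-class
#' @export
setGeneric("volumeML", function(x) standardGeneric("volumeML"))

#' @rdname TerritoryAtlas-class
#' @param x an object.
#' @export
setGeneric("territoryLabels", function(x) standardGeneric("territoryLabels"))
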