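#' Construct a BoldSeries
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param voxelSize numeric(3), mm.
#' @param tr numeric(1), seconds.
#' @param brainMask logical 3D array; defaults to all-TRUE.
#' @return A [BoldSeries-class].
#' @examples
#' b <- BoldSeries(array(rnorm(4 * 4 * 2 * 10), c(4, 4, 2, 10)),
#'                 voxelSize = c(3, 3, 4), tr = 0.4)
#' nFrames(b)
#' @export
BoldSeries <- function(data, voxelSize, tr, brainMask = NULL) {
  if (is.null(brainMask))
    brainMask <- array(TRUE, dim(data)[1:3])
  new("BoldSeries", data = data, voxelSize = as.numeric(voxelSize),
      tr = as.numeric(tr), brainMask = array(as.logical(brainMask), dim(brainMask)))
}

#' Construct a MotionTrace
#'
#' @param translations n x 3 matrix, mm.
#' @param rotations n x 3 matrix, radians.
#' @param tr numeric(1), seconds.
#' @return A [MotionTrace-class].
#' @export
MotionTrace <- function(translations, rotations, tr) {
  new("MotionTrace", translations = as.matrix(translations),
      rotations = as.matrix(rotations), tr = as.numeric(tr))
}

#' Construct a TerritoryAtlas
#'
#' @param labels integer 3D array (0 = background).
#' @param territoryNames named character vector mapping label integers
#'   (as strings) to names; autogenerated when NULL.
#' @return A [TerritoryAtlas-class].
#' @export
TerritoryAtlas <- function(labels, territoryNames = NULL) {
  labels <- array(as.integer(labels), dim(labels))
  if (is.null(territoryNames)) {
    labs <- sort(unique(as.vector(labels)))
    labs <- labs[labs > 0]
    territoryNames <- stats::setNames(paste0("territory", labs), as.character(labs))
  }
  new("TerritoryAtlas", labels = labels, territoryNames = territoryNames)
}

#' @rdname BoldSeries-class
setMethod("boldData", "BoldSeries", function(x) x@data)

#' @rdname BoldSeries-class
setMethod("brainMask", "BoldSeries", function(x) x@brainMask)

#' @rdname BoldSeries-class
setMethod("nFrames", "BoldSeries", function(x) dim(x@data)[4])

#' @rdname BoldSeries-class
setMethod("nFrames", "MotionTrace", function(x) nrow(x@translations))

#' @rdname BoldSeries-class
setMethod("repetitionTime", "BoldSeries", function(x) x@tr)

#' @rdname BoldSeries-class
setMethod("repetitionTime", "LagMap", function(x) x@tr)

#' @rdname BoldSeries-class
setMethod("repetitionTime", "ReferenceSeries", function(x) x@tr)

#' @rdname BoldSeries-class
setMethod("voxelDims", "BoldSeries", function(x) x@voxelSize)

#' @rdname BoldSeries-class
setMethod("voxelDims", "LagMap", function(x) x@voxelSize)

#' @rdname LagMap-class
setMethod("lagValues", "LagMap", function(x) x@lags)

#' @rdname LagMap-class
setMethod("peakCorrelation", "LagMap", function(x) x@peakR)

#' @rdname LagMap-class
setMethod("validMask", "LagMap", function(x) x@valid)

#' @rdname NullCalibration-class
setMethod("rThreshold", "NullCalibration", function(x) x@rThreshold)

#' @rdname DelineationResult-class
setMethod("lesionMask", "DelineationResult", function(x) x@lesionMask)

#' @rdname DelineationResult-class
setMethod("volumeML", "DelineationResult", function(x) x@volumeML)

#' @rdname TerritoryAtlas-class
setMethod("territoryLabels", "TerritoryAtlas", function(x) {
  labs <- sort(unique(as.vector(x@labels)))
  as.integer(labs[labs > 0])
})

setMethod("show", "BoldSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("BoldSeries: %d x %d x %d voxels, %d frames\n", d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size: %s mm; TR: %g s; duration: %g s\n",
              paste(object@voxelSize, collapse = " x "), object@tr, d[4] * object@tr))
  cat(sprintf("  brain mask: %d voxels\n", sum(object@brainMask)))
})

setMethod("show", "MotionTrace", function(object) {
  cat(sprintf("MotionTrace: %d frames at TR %g s\n", nrow(object@translations), object@tr))
  fd <- framewiseDisplacement(object)
  cat(sprintf("  mean FD: %.4f mm (x10: %.4f)\n", fd$meanFD, fd$meanFDx10))
})

setMethod("show", "LagMap", function(object) {
  nb <- sum(!is.na(object@lags))
  cat(sprintf("LagMap: %s grid, %d mapped voxels (%d significant)\n",
              paste(dim(object@lags), collapse = " x "), nb, sum(object@valid)))
  cat(sprintf("  tracking range: [%g, %g] s at TR %g s\n",
              object@trackingRange[1], object@trackingRange[2], object@tr))
})

setMethod("show", "NullCalibration", function(object) {
  cat(sprintf("NullCalibration: %d surrogates, alpha %.3f -> r threshold %.4f\n",
              object@nNull, object@alpha, object@rThreshold))
})

setMethod("show", "DelineationResult", function(object) {
  cat(sprintf("DelineationResult (%s): threshold > %g s, %.2f mL, %d cluster(s)\n",
              object@mapKind, object@threshold, object@volumeML, object@nClusters))
  cat(sprintf("  searched territory labels: %s\n",
              paste(object@affectedLabels, collapse = ", ")))
})

setMethod("show", "TerritoryAtlas", function(object) {
  labs <- territoryLabels(object)
  cat(sprintf("TerritoryAtlas: %s grid, %d territories\n",
              paste(dim(object@labels), collapse = " x "), length(labs)))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf("SyntheticConfig: %s voxels at %s mm, %d frames, TR %g s\n",
              paste(object@gridShape, collapse = "x"),
              paste(object@voxelSize, collapse = "x"),
              object@nFrames, object@tr))
  cat(sprintf("  sLFO band %g-%g Hz; snr %g; lesion fraction %g; seed %d\n",
              object@slfoBand[1], object@slfoBand[2], object@snr,
              object@lesionFraction, object@seed))
})
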