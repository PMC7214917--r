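#' @import methods
NULL

#' 4D BOLD time series with grid geometry
#'
#' Central container of the pipeline: a 4D intensity array (x, y, z, t)
#' together with the voxel size in mm, the repetition time (TR) in seconds,
#' and a binary brain (parenchyma) mask on the same spatial grid.
#'
#' @slot data 4D numeric array, dimensions (x, y, z, t).
#' @slot voxelSize numeric(3), voxel edge lengths in mm.
#' @slot tr numeric(1), repetition time in seconds.
#' @slot brainMask logical 3D array matching the spatial grid.
#'
#' @seealso [BoldSeries()] for construction, [discardInitial()],
#'   [bandPass()], [mapLags()]
#' @export
setClass("BoldSeries",
  representation(
    data = "array",
    voxelSize = "numeric",
    tr = "numeric",
    brainMask = "array"
  )
)

setValidity("BoldSeries", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "data must be a 4D array (x, y, z, t)")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 strictly positive values (mm)")
  if (length(object@tr) != 1L || object@tr <= 0)
    msg <- c(msg, "tr must be a single positive number (s)")
  if (length(dim(object@data)) == 4L &&
      !identical(dim(object@brainMask), dim(object@data)[1:3]))
    msg <- c(msg, "brainMask shape must equal the spatial shape of data")
  if (length(msg)) msg else TRUE
})

#' Rigid-body head motion trace
#'
#' Per-frame rigid-body motion parameters: three translations (mm) and
#' three rotations (radians). Framewise displacement and its summaries are
#' computed on demand by [framewiseDisplacement()].
#'
#' @slot translations n x 3 numeric matrix (mm).
#' @slot rotations n x 3 numeric matrix (radians).
#' @slot tr numeric(1), sampling interval in seconds.
#' @export
setClass("MotionTrace",
  representation(
    translations = "matrix",
    rotations = "matrix",
    tr = "numeric"
  )
)

setValidity("MotionTrace", function(object) {
  msg <- character()
  if (ncol(object@translations) != 3L) msg <- c(msg, "translations must have 3 columns")
  if (ncol(object@rotations) != 3L) msg <- c(msg, "rotations must have 3 columns")
  if (nrow(object@translations) != nrow(object@rotations))
    msg <- c(msg, "translations and rotations must have the same number of frames")
  if (length(object@tr) != 1L || object@tr <= 0) msg <- c(msg, "tr must be positive")
  if (length(msg)) msg else TRUE
})

#' Labeled vascular-territory atlas
#'
#' Integer-labeled 3D map of vascular territories (0 = background) plus a
#' label-to-name mapping. Territories are non-overlapping by construction.
#'
#' @slot labels integer 3D array; 0 marks background.
#' @slot territoryNames named character vector; names are label integers as
#'   strings.
#' @export
setClass("TerritoryAtlas",
  representation(
    labels = "array",
    territoryNames = "character"
  )
)

setValidity("TerritoryAtlas", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L) msg <- c(msg, "labels must be a 3D array")
  if (any(object@labels < 0)) msg <- c(msg, "labels must be non-negative integers")
  labs <- sort(unique(as.vector(object@labels)))
  labs <- labs[labs > 0]
  if (length(labs) && !all(as.character(labs) %in% names(object@territoryNames)))
    msg <- c(msg, "every non-zero label needs an entry in territoryNames")
  if (length(msg)) msg else TRUE
})

#' Ground truth for a synthetic subject
#'
#' The generator's true per-voxel lag field (seconds), lesion / reference /
#' diffusion-lesion masks, territory atlas, the common systemic
#' low-frequency oscillation (sLFO) source signal, and the per-voxel signal
#' amplitude field. Used for recovery testing of the lag-mapping stages.
#'
#' @slot lagField 3D numeric array of true lags in seconds (0 outside brain).
#' @slot lesionMask logical 3D array, the hypoperfusion (delay) lesion.
#' @slot sinusMask logical 3D array, venous-sinus reference region (outside
#'   the parenchyma).
#' @slot territoryAtlas a [TerritoryAtlas-class].
#' @slot dwiMask logical 3D array, the diffusion (infarct core) lesion,
#'   a subset of lesionMask.
#' @slot slfoSignal numeric, the zero-lag sLFO source series.
#' @slot amplitudeField 3D numeric array of positive signal amplitudes.
#' @export
setClass("GroundTruth",
  representation(
    lagField = "array",
    lesionMask = "array",
    sinusMask = "array",
    territoryAtlas = "TerritoryAtlas",
    dwiMask = "array",
    slfoSignal = "numeric",
    amplitudeField = "array"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  dm <- dim(object@lagField)
  for (s in c("lesionMask", "sinusMask", "dwiMask", "amplitudeField"))
    if (!identical(dim(slot(object, s)), dm))
      msg <- c(msg, sprintf("%s shape must match lagField", s))
  if (any(object@dwiMask & !object@lesionMask))
    msg <- c(msg, "dwiMask must be a subset of lesionMask")
  brain <- object@territoryAtlas@labels > 0
  if (identical(dim(brain), dm)) {
    if (any(object@lesionMask & !brain))
      msg <- c(msg, "lesionMask must lie inside the brain (labeled) region")
    if (any(object@sinusMask & brain))
      msg <- c(msg, "sinusMask must be disjoint from brain parenchyma labels")
  }
  if (any(object@amplitudeField < 0))
    msg <- c(msg, "amplitudeField must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Reference time series for lag mapping
#'
#' Mean BOLD time course over a reference mask (canonically the major
#' venous sinuses, which lie outside hypoperfusable parenchyma).
#'
#' @slot values numeric series.
#' @slot tr numeric(1), seconds.
#' @slot sourceMaskSize integer(1), number of voxels averaged.
#' @export
setClass("ReferenceSeries",
  representation(
    values = "numeric",
    tr = "numeric",
    sourceMaskSize = "integer"
  )
)

setValidity("ReferenceSeries", function(object) {
  msg <- character()
  if (!all(is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (object@tr <= 0) msg <- c(msg, "tr must be positive")
  if (object@sourceMaskSize < 1L) msg <- c(msg, "sourceMaskSize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Null calibration for the cross-correlation threshold
#'
#' Distribution of maximal cross-correlations between the reference and
#' surrogate series with the reference's amplitude spectrum but randomized
#' phases, plus the derived significance threshold: the empirical
#' (1 - alpha) quantile of the surrogate maxima.
#'
#' @slot nullMaxR numeric, one maximal correlation per surrogate.
#' @slot rThreshold numeric(1), the empirical (1 - alpha) quantile.
#' @slot alpha numeric(1) in (0, 1).
#' @slot nNull integer(1), number of surrogates.
#' @slot seed integer(1), RNG seed used for the surrogates.
#' @export
setClass("NullCalibration",
  representation(
    nullMaxR = "numeric",
    rThreshold = "numeric",
    alpha = "numeric",
    nNull = "integer",
    seed = "integer"
  )
)

setValidity("NullCalibration", function(object) {
  msg <- character()
  if (object@alpha <= 0 || object@alpha >= 1) msg <- c(msg, "alpha must be in (0,1)")
  if (length(object@nullMaxR) != object@nNull)
    msg <- c(msg, "nullMaxR length must equal nNull")
  q <- stats::quantile(object@nullMaxR, 1 - object@alpha, names = FALSE, type = 7)
  if (is.finite(q) && abs(q - object@rThreshold) > 1e-8)
    msg <- c(msg, "rThreshold must be the empirical (1-alpha) quantile of nullMaxR")
  if (length(msg)) msg else TRUE
})

#' BOLD delay (hemodynamic lag) map
#'
#' Per-voxel time shift (seconds) maximizing the cross-correlation with the
#' reference, the peak correlation itself, and a validity mask marking
#' voxels whose peak correlation passed the null threshold. Lags of
#' sub-significance voxels are retained but flagged invalid.
#'
#' @slot lags 3D numeric array of lags in seconds (NA outside brain).
#' @slot peakR 3D numeric array of peak correlations in [-1, 1].
#' @slot valid logical 3D array, TRUE where peakR passed the threshold.
#' @slot tr numeric(1), seconds.
#' @slot trackingRange numeric(2), searched lag range in seconds.
#' @slot voxelSize numeric(3), mm (carried for volume computations).
#' @export
setClass("LagMap",
  representation(
    lags = "array",
    peakR = "array",
    valid = "array",
    tr = "numeric",
    trackingRange = "numeric",
    voxelSize = "numeric"
  )
)

setValidity("LagMap", function(object) {
  msg <- character()
  if (!identical(dim(object@lags), dim(object@peakR)) ||
      !identical(dim(object@lags), dim(object@valid)))
    msg <- c(msg, "lags, peakR and valid must share one 3D shape")
  if (length(object@trackingRange) != 2L ||
      object@trackingRange[1] > object@trackingRange[2])
    msg <- c(msg, "trackingRange must be an increasing pair of seconds")
  lv <- object@lags[object@valid & !is.na(object@lags)]
  if (length(lv) && (any(lv < object@trackingRange[1] - 1e-9) ||
                     any(lv > object@trackingRange[2] + 1e-9)))
    msg <- c(msg, "valid lags must lie within trackingRange")
  rv <- object@peakR[!is.na(object@peakR)]
  if (length(rv) && any(abs(rv) > 1 + 1e-8))
    msg <- c(msg, "peakR must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Result of automated perfusion-lesion delineation
#'
#' Binary lesion mask obtained by thresholding a delay-type map inside the
#' affected vascular territory, with small clusters removed, plus the mask
#' volume in mL.
#'
#' @slot lesionMask logical 3D array.
#' @slot threshold numeric(1), seconds (value > threshold selects voxels).
#' @slot volumeML numeric(1), voxel count x voxel volume / 1000.
#' @slot affectedLabels integer, territory labels searched.
#' @slot mapKind character(1), "bold_delay" or "tmax".
#' @slot nClusters integer(1), clusters surviving the size filter.
#' @export
setClass("DelineationResult",
  representation(
    lesionMask = "array",
    threshold = "numeric",
    volumeML = "numeric",
    affectedLabels = "integer",
    mapKind = "character",
    nClusters = "integer"
  )
)

setValidity("DelineationResult", function(object) {
  msg <- character()
  if (object@volumeML < 0) msg <- c(msg, "volumeML must be non-negative")
  if (!object@mapKind %in% c("bold_delay", "tmax"))
    msg <- c(msg, 'mapKind must be "bold_delay" or "tmax"')
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic BOLD cohort generator
#'
#' Holds the acquisition constants (TR 0.4 s, 850 frames, sLFO band
#' 0.01-0.15 Hz) and the generator's free choices: grid, voxel size, lag
#' ranges for normal tissue and the lesion, lesion size, signal-to-noise
#' ratio (sLFO amplitude over noise SD), number of vascular territories,
#' motion amplitude, and the seed. See [syntheticConfig()].
#'
#' @slot gridShape integer(3) voxels.
#' @slot voxelSize numeric(3) mm.
#' @slot tr numeric(1) seconds.
#' @slot nFrames integer(1).
#' @slot slfoBand numeric(2) Hz, strictly inside (0, Nyquist).
#' @slot lagRangeNormal numeric(2) seconds.
#' @slot lagRangeLesion numeric(2) seconds.
#' @slot lesionFraction numeric(1) in (0, 1), of brain volume.
#' @slot snr numeric(1) > 0.
#' @slot nTerritories integer(1) >= 2.
#' @slot motionAmplitude numeric(1) >= 0, mm.
#' @slot maxGradient numeric(1) > 0, max lag difference (s) between
#'   6-adjacent non-lesion voxels.
#' @slot seed integer(1).
#' @export
setClass("SyntheticConfig",
  representation(
    gridShape = "integer",
    voxelSize = "numeric",
    tr = "numeric",
    nFrames = "integer",
    slfoBand = "numeric",
    lagRangeNormal = "numeric",
    lagRangeLesion = "numeric",
    lesionFraction = "numeric",
    snr = "numeric",
    nTerritories = "integer",
    motionAmplitude = "numeric",
    maxGradient = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 4L))
    msg <- c(msg, "gridShape must be 3 integers >= 4")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive reals (mm)")
  if (object@tr <= 0) msg <- c(msg, "tr must be positive")
  if (object@nFrames < 8L) msg <- c(msg, "nFrames must be >= 8")
  nyq <- 1 / (2 * object@tr)
  if (length(object@slfoBand) != 2L || object@slfoBand[1] <= 0 ||
      object@slfoBand[2] >= nyq || object@slfoBand[1] >= object@slfoBand[2])
    msg <- c(msg, "slfoBand must lie strictly inside (0, Nyquist)")
  for (s in c("lagRangeNormal", "lagRangeLesion")) {
    r <- slot(object, s)
    if (length(r) != 2L || r[1] >= r[2]) msg <- c(msg, sprintf("%s must be increasing", s))
    if (any(abs(r) >= 20)) msg <- c(msg, sprintf("%s must lie strictly inside +/-20 s", s))
  }
  if (object@lesionFraction <= 0 || object@lesionFraction >= 1)
    msg <- c(msg, "lesionFraction must be in (0,1)")
  if (object@snr <= 0) msg <- c(msg, "snr must be positive")
  if (object@nTerritories < 2L) msg <- c(msg, "nTerritories must be >= 2")
  if (object@motionAmplitude < 0) msg <- c(msg, "motionAmplitude must be >= 0")
  if (object@maxGradient <= 0) msg <- c(msg, "maxGradient must be positive")
  if (length(msg)) msg else TRUE
})

#' Configuration of the scan-length experiment
#'
#' Bundles the cohort generator settings with the experiment parameters:
#' scan-segment fractions, delay thresholds for delineation, the null
#' calibration (alpha, number of surrogates), the lag tracking range, and
#' the master seed. See [experimentConfig()].
#'
#' @slot cohort a [SyntheticConfig-class].
#' @slot nSubjects integer(1) >= 1.
#' @slot fractions numeric, ordered scan fractions; must contain 1.0.
#' @slot thresholdsBold numeric, ascending delay thresholds in seconds.
#' @slot thresholdTmax numeric(1), seconds.
#' @slot alpha numeric(1) in (0,1).
#' @slot nNull integer(1).
#' @slot maxLag numeric(1), tracking half-range in seconds.
#' @slot nDiscard integer(1), initial frames removed.
#' @slot minClusterML numeric(1), cluster-size filter for delineation.
#' @slot seed integer(1).
#' @export
setClass("ExperimentConfig",
  representation(
    cohort = "SyntheticConfig",
    nSubjects = "integer",
    fractions = "numeric",
    thresholdsBold = "numeric",
    thresholdTmax = "numeric",
    alpha = "numeric",
    nNull = "integer",
    maxLag = "numeric",
    nDiscard = "integer",
    minClusterML = "numeric",
    seed = "integer"
  )
)

setValidity("ExperimentConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  if (!any(abs(object@fractions - 1) < 1e-12))
    msg <- c(msg, "fractions must contain 1.0 (the reference segment)")
  if (is.unsorted(object@fractions, strictly = TRUE))
    msg <- c(msg, "fractions must be strictly increasing")
  if (is.unsorted(object@thresholdsBold, strictly = TRUE))
    msg <- c(msg, "thresholdsBold must be strictly increasing")
  if (object@alpha <= 0 || object@alpha >= 1) msg <- c(msg, "alpha must be in (0,1)")
  if (object@nNull < 100L) msg <- c(msg, "nNull must be >= 100")
  if (object@maxLag <= 0) msg <- c(msg, "maxLag must be positive")
  if (object@nDiscard < 0L) msg <- c(msg, "nDiscard must be >= 0")
  if (length(msg)) msg else TRUE
})
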