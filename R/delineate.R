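#' Find the vascular territory affected by the stroke
#'
#' The affected territory is where the acute diffusion (DWI) lesion
#' sits: every atlas label containing at least `minFraction` of the DWI
#' lesion voxels is returned (so lesions straddling a border yield a
#' label union). If no label reaches the fraction, the single label with
#' the largest overlap is returned, so the result is never empty.
#'
#' @param atlas a [TerritoryAtlas-class].
#' @param dwiMask non-empty logical 3D array on the same grid.
#' @param minFraction minimum fraction of DWI voxels (default 0.05).
#' @return Sorted integer vector of affected labels.
#' @export
affectedTerritory <- function(atlas, dwiMask, minFraction = 0.05) {
  if (!identical(dim(atlas@labels), dim(dwiMask))) stop("grid mismatch")
  labs <- atlas@labels[dwiMask > 0]
  if (!length(labs)) stop("dwiMask is empty")
  labs <- labs[labs > 0]
  if (!length(labs)) stop("DWI lesion lies entirely outside the atlas")
  tab <- table(labs)
  frac <- tab / sum(dwiMask > 0)
  hit <- as.integer(names(frac)[frac >= minFraction])
  if (!length(hit)) hit <- as.integer(names(tab)[which.max(tab)])
  sort(hit)
}

#' Delineate a perfusion lesion on a delay-type map
#'
#' Automated delineation: searches the affected vascular territory for
#' voxels whose map value strictly exceeds the threshold (`> 0`, `> 2.3`
#' and `> 4.6` s are the conventional delay thresholds; `> 6` s for
#' Tmax-type maps), removes connected components (26-connectivity)
#' smaller than `minClusterML`, and reports the surviving mask and its
#' volume. For [LagMap-class] inputs only voxels that passed the
#' significance threshold participate; a plain numeric array is treated
#' as a Tmax-like map.
#'
#' @param map a [LagMap-class] or numeric 3D array.
#' @param threshold seconds; voxels with value > threshold are candidates.
#' @param territoryLabels integer labels to search (from
#'   [affectedTerritory()]).
#' @param atlas a [TerritoryAtlas-class].
#' @param minClusterML minimum cluster volume in mL (default 1).
#' @param voxelSize numeric(3) mm; required for array input, taken from
#'   the map otherwise.
#' @param useValidOnly restrict LagMap input to significant voxels
#'   (default TRUE).
#' @return A [DelineationResult-class]; an empty mask is a legal result.
#' @export
delineateLesion <- function(map, threshold, territoryLabels, atlas,
                            minClusterML = 1, voxelSize = NULL,
                            useValidOnly = TRUE) {
  if (is(map, "LagMap")) {
    vals <- map@lags
    if (useValidOnly) vals[!map@valid] <- NA_real_
    if (is.null(voxelSize)) voxelSize <- map@voxelSize
    kind <- "bold_delay"
  } else {
    vals <- map
    if (is.null(voxelSize)) stop("voxelSize is required for array maps")
    kind <- "tmax"
  }
  if (!identical(dim(vals), dim(atlas@labels))) stop("grid mismatch")
  territory <- array(atlas@labels %in% territoryLabels, dim(vals))
  cand <- !is.na(vals) & vals > threshold & territory
  comp <- labelComponents(cand, 26L)
  voxML <- prod(voxelSize) / 1000
  keepMask <- array(FALSE, dim(vals))
  nKeep <- 0L
  if (any(cand)) {
    sizes <- tabulate(comp[comp > 0L])
    keepIds <- which(sizes * voxML >= minClusterML)
    nKeep <- length(keepIds)
    if (nKeep) keepMask <- array(comp %in% keepIds, dim(vals))
  }
  new("DelineationResult", lesionMask = keepMask,
      threshold = as.numeric(threshold),
      volumeML = lesionVolume(keepMask, voxelSize),
      affectedLabels = as.integer(sort(territoryLabels)),
      mapKind = kind, nClusters = nKeep)
}

#' Lesion volume in mL
#'
#' @param mask logical/binary 3D array.
#' @param voxelSize numeric(3) mm.
#' @return Voxel count times voxel volume (mm^3) / 1000.
#' @examples
#' lesionVolume(array(TRUE, c(10, 10, 10)), c(1, 1, 1)) # 1 mL
#' @export
lesionVolume <- function(mask, voxelSize) {
  sum(mask > 0) * prod(voxelSize) / 1000
}
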