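#' NIfTI and TSV input/output
#'
#' Thin wrappers over RNifti for the pipeline's file interfaces: 4D BOLD
#' series, 3D masks/atlases, float lag maps, and the 6-column rigid-motion
#' TSV (trans_x, trans_y, trans_z in mm; rot_x, rot_y, rot_z in radians).
#'
#' @param series a [BoldSeries-class].
#' @param path file path (.nii or .nii.gz).
#' @name bold-io
NULL

#' @rdname bold-io
#' @export
writeBoldNifti <- function(series, path) {
  img <- RNifti::asNifti(series@data)
  RNifti::pixdim(img) <- c(series@voxelSize, series@tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname bold-io
#' @param brainMask optional logical 3D array; all-TRUE when NULL.
#' @export
readBoldNifti <- function(path, brainMask = NULL) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- array(as.numeric(img), dim(img))
  BoldSeries(arr, voxelSize = pd[1:3], tr = pd[4], brainMask = brainMask)
}

#' @rdname bold-io
#' @param mask logical or integer 3D array.
#' @param voxelSize numeric(3), mm.
#' @export
writeMaskNifti <- function(mask, voxelSize, path) {
  img <- RNifti::asNifti(array(as.integer(mask), dim(mask)))
  RNifti::pixdim(img) <- voxelSize
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname bold-io
#' @export
readMaskNifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.integer(img), dim(img))
}

#' @rdname bold-io
#' @param volume numeric 3D array (e.g. a lag field), written as float32.
#' @export
writeVolumeNifti <- function(volume, voxelSize, path) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- voxelSize
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname bold-io
#' @export
readVolumeNifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}

#' @rdname bold-io
#' @param trace a [MotionTrace-class].
#' @export
writeMotionTSV <- function(trace, path) {
  df <- data.frame(trace@translations, trace@rotations)
  names(df) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname bold-io
#' @param tr numeric(1), seconds.
#' @export
readMotionTSV <- function(path, tr) {
  df <- utils::read.delim(path)
  need <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  if (!all(need %in% names(df))) stop("motion TSV must have columns: ",
                                      paste(need, collapse = ", "))
  MotionTrace(as.matrix(df[, need[1:3]]), as.matrix(df[, need[4:6]]), tr)
}

# Write one subject's files (used by generateCohort).
writeSubjectBundle <- function(sub, dir) {
  vs <- sub$bold@voxelSize
  writeBoldNifti(sub$bold, file.path(dir, "bold.nii.gz"))
  writeMaskNifti(sub$bold@brainMask, vs, file.path(dir, "brain_mask.nii.gz"))
  tr <- sub$truth
  writeMaskNifti(tr@sinusMask, vs, file.path(dir, "sinus_mask.nii.gz"))
  writeMaskNifti(tr@lesionMask, vs, file.path(dir, "lesion_mask.nii.gz"))
  writeMaskNifti(tr@dwiMask, vs, file.path(dir, "dwi_mask.nii.gz"))
  writeMaskNifti(tr@territoryAtlas@labels, vs, file.path(dir, "territories.nii.gz"))
  writeVolumeNifti(tr@lagField, vs, file.path(dir, "lag_truth.nii.gz"))
  writeVolumeNifti(tr@amplitudeField, vs, file.path(dir, "amplitude_truth.nii.gz"))
  writeMotionTSV(sub$motion, file.path(dir, "motion.tsv"))
  jsonlite::write_json(
    list(tr = sub$bold@tr, voxelSize = vs,
         nFrames = nFrames(sub$bold),
         territoryNames = as.list(tr@territoryAtlas@territoryNames),
         slfoSignal = tr@slfoSignal),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synthetic subject bundle from disk
#'
#' Inverse of the per-subject writer used by [generateCohort()].
#'
#' @param dir subject directory containing bold.nii.gz, the masks, the
#'   motion TSV and the truth sidecar.
#' @return A list with `bold`, `truth`, `motion` as from [generateSubject()].
#' @export
readSubjectBundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  brain <- readMaskNifti(file.path(dir, "brain_mask.nii.gz")) > 0
  bold <- readBoldNifti(file.path(dir, "bold.nii.gz"), brainMask = brain)
  atlas <- TerritoryAtlas(readMaskNifti(file.path(dir, "territories.nii.gz")),
                          unlist(meta$territoryNames))
  truth <- new("GroundTruth",
               lagField = readVolumeNifti(file.path(dir, "lag_truth.nii.gz")),
               lesionMask = readMaskNifti(file.path(dir, "lesion_mask.nii.gz")) > 0,
               sinusMask = readMaskNifti(file.path(dir, "sinus_mask.nii.gz")) > 0,
               territoryAtlas = atlas,
               dwiMask = readMaskNifti(file.path(dir, "dwi_mask.nii.gz")) > 0,
               slfoSignal = as.numeric(meta$slfoSignal),
               amplitudeField = readVolumeNifti(file.path(dir, "amplitude_truth.nii.gz")))
  motion <- readMotionTSV(file.path(dir, "motion.tsv"), tr = meta$tr)
  list(bold = bold, truth = truth, motion = motion)
}
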