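#' @rdname discardInitial
setMethod("discardInitial", "BoldSeries", function(x, nDiscard) {
  nDiscard <- as.integer(nDiscard)
  nt <- nFrames(x)
  if (nDiscard < 0L) stop("nDiscard must be >= 0")
  if (nDiscard >= nt) stop("nDiscard must leave at least one frame")
  if (nDiscard == 0L) return(x)
  BoldSeries(x@data[, , , (nDiscard + 1L):nt, drop = FALSE],
             voxelSize = x@voxelSize, tr = x@tr, brainMask = x@brainMask)
})

#' @rdname discardInitial
setMethod("discardInitial", "MotionTrace", function(x, nDiscard) {
  nDiscard <- as.integer(nDiscard)
  nt <- nFrames(x)
  if (nDiscard < 0L) stop("nDiscard must be >= 0")
  if (nDiscard >= nt) stop("nDiscard must leave at least one frame")
  if (nDiscard == 0L) return(x)
  MotionTrace(x@translations[(nDiscard + 1L):nt, , drop = FALSE],
              x@rotations[(nDiscard + 1L):nt, , drop = FALSE], x@tr)
})

# Keep only the first nKeep frames.
truncateFrames <- function(x, nKeep) {
  if (is(x, "BoldSeries"))
    return(BoldSeries(x@data[, , , seq_len(nKeep), drop = FALSE],
                      voxelSize = x@voxelSize, tr = x@tr, brainMask = x@brainMask))
  MotionTrace(x@translations[seq_len(nKeep), , drop = FALSE],
              x@rotations[seq_len(nKeep), , drop = FALSE], x@tr)
}

#' Cut a scan into shortened segments
#'
#' Produces truncated copies of a post-discard [BoldSeries-class], one per
#' requested fraction of the original (pre-discard) scan. A segment's
#' frame count is `round(fraction * nOriginal) - nDiscard`, taken as a
#' prefix, and its nominal duration is reported as
#' `round(fraction * nOriginal) * tr` — at 850 frames and TR 0.4 s the
#' fractions 0.2/0.4/0.6/0.8 yield the nominal 68/136/204/272 s segments.
#' (Fractions refer to the original scan; the frames actually analyzed
#' exclude the discarded lead-in, so the nominal duration of a shortened
#' segment exceeds its analyzed duration by `nDiscard * tr`.)
#'
#' @param series [BoldSeries-class] after [discardInitial()].
#' @param fractions numeric vector in (0, 1].
#' @param nOriginal pre-discard frame count.
#' @return Named list (one element per fraction) of lists with `fraction`,
#'   `nFramesSegment`, `duration` (s, nominal) and `series`.
#' @examples
#' full <- BoldSeries(array(rnorm(2 * 2 * 2 * 850), c(2, 2, 2, 850)),
#'                    c(3, 3, 4), 0.4)
#' segs <- makeSegments(discardInitial(full, 25), c(0.2, 1.0), 850)
#' segs[["0.2"]]$duration
#' @export
makeSegments <- function(series, fractions = c(0.2, 0.4, 0.6, 0.8, 1.0),
                         nOriginal = NULL) {
  if (is.null(nOriginal)) stop("nOriginal (pre-discard frame count) is required")
  nDiscard <- nOriginal - nFrames(series)
  if (nDiscard < 0L) stop("series has more frames than nOriginal")
  out <- list()
  for (f in fractions) {
    if (f <= 0 || f > 1) stop("fractions must lie in (0, 1]")
    nNominal <- round(f * nOriginal)
    nSeg <- nNominal - nDiscard
    if (nSeg < 2L) stop(sprintf("fraction %g yields fewer than 2 frames", f))
    out[[format(f)]] <- list(fraction = f,
                             nFramesSegment = as.integer(nSeg),
                             duration = nNominal * series@tr,
                             series = truncateFrames(series, nSeg))
  }
  out
}

#' Regress confounds out of every voxel time course
#'
#' Replaces each voxel series with the residual of an ordinary
#' least-squares fit on the confound columns plus an intercept (the
#' standard rigid-motion nuisance regression: three translations and
#' three rotations). Collinear confound columns are dropped with a
#' warning. Residuals are orthogonal to every retained confound column.
#'
#' @param series a [BoldSeries-class].
#' @param confounds nFrames x k numeric matrix.
#' @return A [BoldSeries-class] of residuals.
#' @export
regressConfounds <- function(series, confounds) {
  confounds <- as.matrix(confounds)
  nt <- nFrames(series)
  if (nrow(confounds) != nt) stop("confound rows must match nFrames")
  # constant columns carry no information beyond the intercept; drop quietly
  keepCol <- apply(confounds, 2L, function(v) stats::sd(v) > 0)
  confounds <- confounds[, keepCol, drop = FALSE]
  D <- cbind(intercept = 1, confounds)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    keep <- qrD$pivot[seq_len(qrD$rank)]
    dropped <- setdiff(seq_len(ncol(D)), keep)
    warning(sprintf("dropping %d collinear confound column(s)", length(dropped)))
    D <- D[, keep, drop = FALSE]
    qrD <- qr(D)
  }
  d <- dim(series@data)
  X <- t(matrix(series@data, prod(d[1:3]), nt)) # frames x voxels
  res <- qr.resid(qrD, X)
  BoldSeries(array(t(res), d), voxelSize = series@voxelSize, tr = series@tr,
             brainMask = series@brainMask)
}

#' Spatially smooth every frame with a Gaussian kernel
#'
#' Per-frame separable 3D Gaussian convolution. The kernel width is given
#' as full width at half maximum in mm and converted to a per-axis sigma
#' in voxels (sigma = FWHM / 2.3548 / voxel size). Zero-padded at the
#' volume boundary; no mask renormalization.
#'
#' @param series a [BoldSeries-class].
#' @param fwhm kernel FWHM in mm; 0 is the identity.
#' @return A smoothed [BoldSeries-class].
#' @export
smoothSpatial <- function(series, fwhm = 6) {
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (fwhm == 0) return(series)
  sigmaVox <- fwhm / (2 * sqrt(2 * log(2))) / series@voxelSize
  d <- dim(series@data)
  out <- series@data
  # one banded matmul per axis, all frames at once
  for (ax in 1:3) {
    if (sigmaVox[ax] <= 0) next
    k <- gaussianKernel1d(sigmaVox[ax])
    if (length(k) == 1L) next
    K <- convolutionMatrix(d[ax], k)
    perm <- c(ax, setdiff(1:4, ax))
    v <- aperm(out, perm)
    dm <- dim(v)
    v <- K %*% matrix(v, dm[1], prod(dm[-1]))
    dim(v) <- dm
    out <- aperm(v, order(perm))
  }
  BoldSeries(out, voxelSize = series@voxelSize, tr = series@tr,
             brainMask = series@brainMask)
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering of every voxel time
#' course, order 2 per direction. Zero phase matters here: any phase
#' distortion would bias the lag estimates the filtered data feed into.
#' The temporal mean is removed.
#'
#' @param series a [BoldSeries-class].
#' @param low,high band edges in Hz, 0 < low < high < Nyquist.
#' @return A filtered [BoldSeries-class].
#' @export
bandPass <- function(series, low = 0.01, high = 0.15) {
  nyq <- 1 / (2 * series@tr)
  if (!(low > 0 && low < high && high < nyq))
    stop("band must satisfy 0 < low < high < Nyquist")
  bf <- signal::butter(2, c(low, high) / nyq, type = "pass")
  d <- dim(series@data)
  X <- matrix(series@data, prod(d[1:3]), d[4])
  X <- X - rowMeans(X)
  # pad with about one period of the low cutoff to damp edge transients
  padlen <- ceiling(1 / (low * series@tr))
  Y <- filtfiltRows(bf$b, bf$a, X, padlen = padlen)
  Y <- Y - rowMeans(Y)
  BoldSeries(array(Y, d), voxelSize = series@voxelSize, tr = series@tr,
             brainMask = series@brainMask)
}

#' Framewise displacement
#'
#' Per-frame head-motion summary: the sum of absolute frame-to-frame
#' translation changes plus the absolute rotation changes converted to mm
#' of arc on a sphere (default radius 50 mm). The first frame is
#' undefined (NA). A x10 rescaled mean is also returned, a convention
#' used to put FD on a scale comparable with other model coefficients.
#'
#' @param trace a [MotionTrace-class].
#' @param headRadius sphere radius in mm.
#' @return List with `fd` (numeric, NA first), `meanFD` and `meanFDx10`.
#' @export
framewiseDisplacement <- function(trace, headRadius = 50) {
  nt <- nFrames(trace)
  if (nt < 2L) stop("need at least 2 frames")
  dt <- abs(diff(trace@translations))
  dr <- abs(diff(trace@rotations))
  fd <- c(NA_real_, rowSums(dt) + headRadius * rowSums(dr))
  meanFD <- mean(fd, na.rm = TRUE)
  list(fd = fd, meanFD = meanFD, meanFDx10 = 10 * meanFD)
}

#' DVARS
#'
#' Frame-to-frame root-mean-square intensity change over brain voxels:
#' `DVARS_t = sqrt(mean_brain((I_t - I_{t-1})^2))` for t >= 2, NA for the
#' first frame.
#'
#' @param series a [BoldSeries-class] with a non-empty brain mask.
#' @return List with `dvars` (numeric, NA first) and `meanDVARS`.
#' @export
dvars <- function(series) {
  if (!any(series@brainMask)) stop("brain mask is empty")
  nt <- nFrames(series)
  if (nt < 2L) stop("need at least 2 frames")
  d <- dim(series@data)
  X <- matrix(series@data, prod(d[1:3]), nt)[as.vector(series@brainMask), , drop = FALSE]
  dv <- c(NA_real_, sqrt(colMeans((X[, -1L, drop = FALSE] -
                                   X[, -nt, drop = FALSE])^2)))
  list(dvars = dv, meanDVARS = mean(dv, na.rm = TRUE))
}

#' Run the fixed preprocessing chain on one series
#'
#' Applies, in this fixed order: initial-frame discard, rigid-motion
#' confound regression, motion QC (FD on the truncated trace, DVARS on
#' the residuals before smoothing), spatial smoothing, and zero-phase
#' band-pass filtering. The order is part of the method: DVARS is taken
#' after nuisance regression but before smoothing/filtering, and the
#' band-pass comes last so the series entering lag mapping is band
#' limited with no phase distortion.
#'
#' @param series raw [BoldSeries-class].
#' @param motion matching [MotionTrace-class].
#' @param nDiscard initial frames to drop (default 25 = 10 s at TR 0.4 s).
#' @param fwhm smoothing kernel FWHM, mm.
#' @param band numeric(2) Hz.
#' @return List with `series` (filtered [BoldSeries-class]), `motion`
#'   (truncated trace) and `qc` (meanFD, meanFDx10, meanDVARS).
#' @export
preprocessBold <- function(series, motion, nDiscard = 25L, fwhm = 6,
                           band = c(0.01, 0.15)) {
  s <- discardInitial(series, nDiscard)
  m <- discardInitial(motion, nDiscard)
  s <- regressConfounds(s, cbind(m@translations, m@rotations))
  fd <- framewiseDisplacement(m)
  dv <- dvars(s)
  s <- smoothSpatial(s, fwhm)
  s <- bandPass(s, band[1], band[2])
  list(series = s, motion = m,
       qc = list(meanFD = fd$meanFD, meanFDx10 = fd$meanFDx10,
                 meanDVARS = dv$meanDVARS))
}
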