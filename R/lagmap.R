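#' Extract the reference time series from a mask
#'
#' Averages the BOLD signal across all voxels of a reference mask —
#' canonically the major venous sinuses, which lie outside the brain
#' parenchyma and therefore cannot themselves be hypoperfused.
#'
#' @param series a [BoldSeries-class].
#' @param sinusMask non-empty logical 3D array on the same grid.
#' @return A [ReferenceSeries-class].
#' @export
extractReference <- function(series, sinusMask) {
  d <- dim(series@data)
  if (!identical(dim(sinusMask), d[1:3])) stop("mask grid mismatch")
  idx <- which(sinusMask)
  if (!length(idx)) stop("reference mask is empty")
  X <- matrix(series@data, prod(d[1:3]), d[4])
  vals <- if (length(idx) == 1L) X[idx, ] else colMeans(X[idx, , drop = FALSE])
  new("ReferenceSeries", values = as.numeric(vals), tr = series@tr,
      sourceMaskSize = length(idx))
}

# Core engine: Pearson correlation between every row of X (series in rows)
# and the reference, at every integer shift d in -D..D. Correlation is
# computed on the truncated overlap (no zero padding), each overlap
# separately mean-centred. Positive d means the row series is delayed
# relative to the reference. Returns r as a matrix nrow(X) x (2D+1) with
# columns ordered by ascending lag; rows with (near-)zero variance in an
# overlap get NA there.
lagCorrelationMatrix <- function(X, ref, D) {
  V <- nrow(X); Tn <- ncol(X)
  if (length(ref) != Tn) stop("series lengths differ")
  if (Tn - D < 3L) stop("series too short for the requested lag range")
  C1 <- rowCumsums(X)
  C2 <- rowCumsums(X^2)
  winSum <- function(C, a, b) {
    if (a == 1L) C[, b] else C[, b] - C[, a - 1L]
  }
  lags <- (-D):D
  R <- matrix(NA_real_, V, length(lags))
  eps <- 1e-12
  for (j in seq_along(lags)) {
    dL <- lags[j]
    if (dL >= 0) { xa <- 1L + dL; xb <- Tn; ra <- 1L; rb <- Tn - dL }
    else { xa <- 1L; xb <- Tn + dL; ra <- 1L - dL; rb <- Tn }
    n <- xb - xa + 1L
    rw <- ref[ra:rb]
    rw <- rw - mean(rw)
    sr2 <- sum(rw^2)
    w <- numeric(Tn)
    w[xa:xb] <- rw
    num <- as.vector(X %*% w)
    s1 <- winSum(C1, xa, xb)
    s2 <- winSum(C2, xa, xb)
    sx2 <- s2 - s1^2 / n
    den <- sqrt(pmax(sx2, 0) * sr2)
    r <- ifelse(sx2 > eps & sr2 > eps, num / den, NA_real_)
    R[, j] <- pmin(pmax(r, -1), 1)
  }
  list(r = R, lags = lags)
}

# Argmax over lags with ties broken toward the smallest |lag| (and toward
# the negative lag between +/-d), by visiting columns in that order with a
# strict > update.
peakLag <- function(R, lags, tr) {
  ord <- order(abs(lags), lags)
  best <- R[, ord[1L]]
  bestLag <- ifelse(is.na(best), NA_real_, lags[ord[1L]])
  for (j in ord[-1L]) {
    rj <- R[, j]
    upd <- !is.na(rj) & (is.na(best) | rj > best)
    best[upd] <- rj[upd]
    bestLag[upd] <- lags[j]
  }
  list(lag = bestLag * tr, r = best)
}

#' Estimate the delay of one series against a reference
#'
#' Shifts the pair over all integer multiples of TR within `maxLag`,
#' computes the Pearson correlation on the (mean-centred) overlapping
#' samples at each shift, and returns the shift maximizing the
#' correlation. Positive lag means the series is delayed relative to the
#' reference. Ties are broken toward the smallest absolute lag. A series
#' with zero variance in an overlap yields an NA (flagged, not an error).
#'
#' @param voxelTs numeric series.
#' @param ref a [ReferenceSeries-class] (or numeric series, with `tr`).
#' @param maxLag tracking half-range in seconds (default 20).
#' @param tr sampling interval when `ref` is a bare numeric series.
#' @return List with `lag` (seconds) and `r` (peak correlation).
#' @examples
#' refv <- sin(2 * pi * 0.05 * (0:299) * 0.4)
#' ref <- new("ReferenceSeries", values = refv, tr = 0.4, sourceMaskSize = 1L)
#' estimateLag(c(rep(0, 10), refv[1:290]), ref, maxLag = 8)
#' @export
estimateLag <- function(voxelTs, ref, maxLag = 20, tr = NULL) {
  if (is(ref, "ReferenceSeries")) { refv <- ref@values; tr <- ref@tr }
  else refv <- as.numeric(ref)
  if (is.null(tr)) stop("tr is required when ref is not a ReferenceSeries")
  D <- as.integer(round(maxLag / tr))
  if (D < 1L) stop("maxLag must be at least one sample")
  cc <- lagCorrelationMatrix(matrix(voxelTs, 1L), refv, D)
  pk <- peakLag(cc$r, cc$lags, tr)
  list(lag = pk$lag[1L], r = pk$r[1L])
}

#' Phase-randomized surrogates of a series
#'
#' Randomizes the Fourier phases of a series while preserving its
#' amplitude spectrum (and hence autocorrelation), yielding surrogates
#' with the same spectral content but no systematic temporal alignment
#' with the original. For band-limited references this is the appropriate
#' null for the maximal lagged correlation: plain sample permutation
#' destroys the autocorrelation and yields an anticonservative threshold.
#'
#' @param x numeric series.
#' @param n number of surrogates.
#' @param seed integer RNG seed.
#' @return n x length(x) matrix, one surrogate per row.
#' @export
phaseRandomize <- function(x, n, seed = 1L) {
  Tn <- length(x)
  F0 <- fft(x)
  amp <- Mod(F0)
  half <- if (Tn %% 2L == 0L) Tn / 2L - 1L else (Tn - 1L) / 2L
  withSeed(seed, {
    out <- matrix(0, n, Tn)
    for (i in seq_len(n)) {
      ph <- stats::runif(half, 0, 2 * pi)
      Fs <- complex(real = numeric(Tn), imaginary = numeric(Tn))
      Fs[1L] <- F0[1L]
      Fs[2L:(half + 1L)] <- amp[2L:(half + 1L)] * exp(1i * ph)
      if (Tn %% 2L == 0L)
        Fs[Tn / 2L + 1L] <- amp[Tn / 2L + 1L] * sample(c(-1, 1), 1L)
      Fs[(Tn - half + 1L):Tn] <- Conj(Fs[(half + 1L):2L])
      out[i, ] <- Re(fft(Fs, inverse = TRUE)) / Tn
    }
    out
  })
}

#' Calibrate the null distribution of the peak correlation
#'
#' Builds surrogate references by phase randomization, runs each through
#' the same lagged-correlation search used for real voxels, and records
#' the maximal correlation per surrogate. The significance threshold is
#' the empirical (1 - alpha) quantile of these maxima, so a voxel whose
#' peak correlation exceeds it would arise by chance with probability
#' about alpha under spectrally matched noise.
#'
#' @param ref a [ReferenceSeries-class].
#' @param maxLag tracking half-range in seconds.
#' @param nNull number of surrogates (>= 100; 10000 for reported maps,
#'   smaller values are adequate for exploration).
#' @param alpha significance level in (0, 1).
#' @param seed integer RNG seed.
#' @return A [NullCalibration-class].
#' @export
calibrateNull <- function(ref, maxLag = 20, nNull = 10000L, alpha = 0.05,
                          seed = 1L) {
  if (nNull < 100L) stop("nNull must be >= 100 for a usable threshold")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  D <- as.integer(round(maxLag / ref@tr))
  S <- phaseRandomize(ref@values, nNull, seed = seed)
  cc <- lagCorrelationMatrix(S, ref@values, D)
  nullMax <- apply(cc$r, 1L, max, na.rm = TRUE)
  thr <- stats::quantile(nullMax, 1 - alpha, names = FALSE, type = 7)
  new("NullCalibration", nullMaxR = as.numeric(nullMax),
      rThreshold = as.numeric(thr), alpha = alpha,
      nNull = as.integer(nNull), seed = as.integer(seed))
}

#' Compute the BOLD delay map
#'
#' Assigns every brain voxel the time shift (integer multiple of TR
#' within the tracking range) that maximizes its cross-correlation with
#' the reference, plus the peak correlation. Voxels whose peak
#' correlation falls below the calibrated null threshold keep their lag
#' but are flagged invalid.
#'
#' @param series preprocessed [BoldSeries-class].
#' @param ref a [ReferenceSeries-class] of matching length.
#' @param calib a [NullCalibration-class].
#' @param maxLag tracking half-range in seconds (default 20).
#' @return A [LagMap-class].
#' @export
mapLags <- function(series, ref, calib, maxLag = 20) {
  d <- dim(series@data)
  if (length(ref@values) != d[4]) stop("reference length must match nFrames")
  D <- as.integer(round(maxLag / series@tr))
  idx <- which(series@brainMask)
  X <- matrix(series@data, prod(d[1:3]), d[4])[idx, , drop = FALSE]
  cc <- lagCorrelationMatrix(X, ref@values, D)
  pk <- peakLag(cc$r, cc$lags, series@tr)
  lags <- array(NA_real_, d[1:3])
  peakR <- array(NA_real_, d[1:3])
  valid <- array(FALSE, d[1:3])
  lags[idx] <- pk$lag
  peakR[idx] <- pk$r
  valid[idx] <- !is.na(pk$r) & pk$r >= calib@rThreshold
  new("LagMap", lags = lags, peakR = peakR, valid = valid, tr = series@tr,
      trackingRange = c(-D, D) * series@tr, voxelSize = series@voxelSize)
}
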