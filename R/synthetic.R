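#' Configure the synthetic BOLD cohort generator
#'
#' Builds a [SyntheticConfig-class] describing one synthetic subject: a 4D
#' BOLD acquisition in which a single band-limited systemic low-frequency
#' oscillation (sLFO) arrives at every voxel with a spatially smooth,
#' known delay. Defaults reproduce the acquisition this pipeline targets:
#' TR 0.4 s, 850 frames (340 s), sLFO band 0.01-0.15 Hz, and a desk-scale
#' 32 x 32 x 16 grid at 3 x 3 x 4 mm. Normal parenchyma carries lags of
#' -2 to +2 s; the lesion carries lags of +3 to +10 s, comfortably inside
#' the +/-20 s tracking range used downstream.
#'
#' @param gridShape integer(3), voxels per axis.
#' @param voxelSize numeric(3), mm.
#' @param tr repetition time, seconds.
#' @param nFrames number of time points.
#' @param slfoBand numeric(2), Hz; must lie strictly inside (0, Nyquist).
#' @param lagRangeNormal numeric(2), seconds, lag range of normal tissue.
#' @param lagRangeLesion numeric(2), seconds, lag range inside the lesion.
#' @param lesionFraction fraction of brain volume occupied by the lesion.
#' @param snr sLFO amplitude over noise standard deviation.
#' @param nTerritories number of vascular-territory labels (>= 2).
#' @param motionAmplitude peak head-motion excursion, mm (0 = motionless).
#' @param maxGradient maximum lag difference (s) between 6-adjacent
#'   non-lesion voxels.
#' @param seed integer RNG seed.
#' @return A validated [SyntheticConfig-class].
#' @examples
#' cfg <- syntheticConfig(gridShape = c(16, 16, 8), nFrames = 200, seed = 7)
#' cfg
#' @export
syntheticConfig <- function(gridShape = c(32L, 32L, 16L),
                            voxelSize = c(3, 3, 4),
                            tr = 0.4,
                            nFrames = 850L,
                            slfoBand = c(0.01, 0.15),
                            lagRangeNormal = c(-2, 2),
                            lagRangeLesion = c(3, 10),
                            lesionFraction = 0.1,
                            snr = 5,
                            nTerritories = 3L,
                            motionAmplitude = 0,
                            maxGradient = 0.6,
                            seed = 1L) {
  new("SyntheticConfig",
      gridShape = as.integer(gridShape), voxelSize = as.numeric(voxelSize),
      tr = as.numeric(tr), nFrames = as.integer(nFrames),
      slfoBand = as.numeric(slfoBand),
      lagRangeNormal = as.numeric(lagRangeNormal),
      lagRangeLesion = as.numeric(lagRangeLesion),
      lesionFraction = as.numeric(lesionFraction), snr = as.numeric(snr),
      nTerritories = as.integer(nTerritories),
      motionAmplitude = as.numeric(motionAmplitude),
      maxGradient = as.numeric(maxGradient), seed = as.integer(seed))
}

#' Generate a band-limited sLFO source signal
#'
#' Synthesizes Gaussian white noise, restricts it to the requested
#' frequency band in the Fourier domain (brick-wall), and normalizes to
#' zero mean and unit variance. The result models the systemic
#' low-frequency oscillation that travels with blood flow and drives
#' BOLD delay mapping.
#'
#' @param nFrames series length.
#' @param tr sampling interval, seconds.
#' @param band numeric(2) Hz, strictly inside (0, Nyquist = 1/(2 tr)).
#' @param seed integer RNG seed.
#' @return Numeric series of length `nFrames`, zero mean, unit variance,
#'   with spectral power confined to `band`.
#' @examples
#' s <- generateSLFO(500, 0.4, c(0.01, 0.15), seed = 1)
#' c(mean(s), var(s))
#' @export
generateSLFO <- function(nFrames, tr, band = c(0.01, 0.15), seed = 1L) {
  nFrames <- as.integer(nFrames)
  nyq <- 1 / (2 * tr)
  if (length(band) != 2L || band[1] <= 0 || band[2] >= nyq || band[1] >= band[2])
    stop("invalid configuration: band must lie strictly inside (0, Nyquist)")
  x <- withSeed(seed, stats::rnorm(nFrames))
  f <- fft(x)
  k <- 0:(nFrames - 1L)
  freq <- pmin(k, nFrames - k) / (nFrames * tr)
  f[freq < band[1] | freq > band[2]] <- 0
  s <- Re(fft(f, inverse = TRUE)) / nFrames
  if (stats::sd(s) == 0) stop("degenerate band: no frequency bin falls inside it")
  s <- s - mean(s)
  s / stats::sd(s)
}

# Ellipsoid mask helper: centre and semi-axes in voxel units.
ellipsoidMask <- function(dims, centre, semi) {
  x <- (seq_len(dims[1]) - centre[1]) / semi[1]
  y <- (seq_len(dims[2]) - centre[2]) / semi[2]
  z <- (seq_len(dims[3]) - centre[3]) / semi[3]
  outer(outer(x^2, y^2, "+"), z^2, "+") <= 1
}

# Apply per-voxel fractional delays to a common source via Fourier phase
# ramps (exact for band-limited signals). `lags` in seconds. Returns a
# matrix length(signal) x length(lags).
delaySignal <- function(signal, lags, tr) {
  n <- length(signal)
  S <- fft(signal)
  k <- 0:(n - 1L)
  k[k > n / 2] <- k[k > n / 2] - n
  if (n %% 2L == 0L) k[n / 2 + 1L] <- 0 # Nyquist bin: no imaginary ramp
  out <- matrix(0, n, length(lags))
  chunk <- max(1L, floor(2e6 / n))
  for (i0 in seq(1L, length(lags), by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, length(lags))
    ramp <- exp(outer(-2i * pi * k / (n * tr), lags[ii]))
    out[, ii] <- Re(stats::mvfft(ramp * S, inverse = TRUE)) / n
  }
  out
}

# Spatially smooth standard-normal-ish random field.
smoothField <- function(dims, sigmaVox) {
  f <- smoothVolume(array(stats::rnorm(prod(dims)), dims), rep(sigmaVox, 3))
  (f - mean(f)) / stats::sd(f)
}

# Geometry shared by every synthetic subject: brain ellipsoid, venous-sinus
# ball behind it, angular-sector territory labels.
subjectGeometry <- function(cfg) {
  d <- cfg@gridShape
  centre <- (d + 1) / 2
  semi <- c(0.40 * d[1], 0.36 * d[2], 0.40 * d[3])
  brain <- ellipsoidMask(d, centre, semi)
  sinCentre <- c(centre[1], centre[2] + 0.42 * d[2], centre[3] - 0.15 * d[3])
  sinus <- ellipsoidMask(d, sinCentre, c(2.2, 2.2, 2.2)) & !brain
  if (!any(sinus)) stop("grid too small to place a venous-sinus reference region")
  co <- arrayInd(which(brain), d)
  theta <- atan2(co[, 2] - centre[2], co[, 1] - centre[1])
  sector <- floor((theta + pi) / (2 * pi) * cfg@nTerritories) %% cfg@nTerritories
  labels <- array(0L, d)
  labels[brain] <- as.integer(sector) + 1L
  atlas <- TerritoryAtlas(labels)
  list(brain = brain, sinus = sinus, atlas = atlas, centre = centre, semi = semi)
}

# Ellipsoidal lesion sized (by bisection on its scale) to occupy
# approximately `fraction` of the brain, centred in one territory.
placeLesion <- function(geom, fraction, d) {
  brainN <- sum(geom$brain)
  target <- fraction * brainN
  if (target < 1) stop("lesionFraction smaller than one voxel on this grid")
  labs <- territoryLabels(geom$atlas)
  lab <- labs[sample.int(length(labs), 1L)]
  vox <- arrayInd(which(geom$atlas@labels == lab), d)
  centre <- colMeans(vox)
  shape <- c(1, 0.85, 0.7) * d / max(d)
  grow <- function(s) sum(ellipsoidMask(d, centre, pmax(s * shape, 0.6)) & geom$brain)
  lo <- 0.1; hi <- max(d)
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (grow(mid) < target) lo <- mid else hi <- mid
  }
  lesion <- ellipsoidMask(d, centre, pmax(hi * shape, 0.6)) & geom$brain
  dwi <- ellipsoidMask(d, centre, pmax(hi * shape * 0.5, 0.6)) & geom$brain & lesion
  if (!any(dwi)) { # guarantee a non-empty core at the lesion centre
    ci <- round(centre)
    dwi[ci[1], ci[2], ci[3]] <- lesion[ci[1], ci[2], ci[3]]
  }
  list(lesion = lesion, dwi = dwi, label = lab)
}

#' Generate one synthetic subject
#'
#' Builds a 4D BOLD series in which every brain voxel receives the same
#' band-limited sLFO, delayed by that voxel's true lag (Fourier phase
#' ramps, exact for band-limited signals) and scaled by a smooth positive
#' amplitude field, plus white noise with standard deviation 1/snr. The
#' true lag field is a smoothed random field over normal parenchyma
#' (`lagRangeNormal`) with an ellipsoidal lesion carrying longer lags
#' (`lagRangeLesion`); venous-sinus voxels carry lag 0 by construction, so
#' the extracted reference is the undelayed source. Motion traces are
#' smooth excursions scaled by `motionAmplitude`; when non-zero, motion-
#' coupled intensity artifacts are added to the data.
#'
#' @param cfg a [SyntheticConfig-class].
#' @return A list with elements `bold` ([BoldSeries-class]), `truth`
#'   ([GroundTruth-class]) and `motion` ([MotionTrace-class]).
#' @examples
#' sub <- generateSubject(syntheticConfig(gridShape = c(12, 12, 6),
#'                                        nFrames = 120, seed = 3))
#' sub$bold
#' @export
generateSubject <- function(cfg) {
  validObject(cfg)
  d <- cfg@gridShape
  tr <- cfg@tr
  nT <- cfg@nFrames
  withSeed(cfg@seed, {
    geom <- subjectGeometry(cfg)
    les <- placeLesion(geom, cfg@lesionFraction, d)

    # true lag field: smooth over parenchyma, re-smoothed until the
    # 6-neighbour gradient bound holds, lesion overwritten with long lags
    lagField <- array(0, d)
    base <- smoothField(d, 3)
    for (i in 1:8) {
      rng <- range(base[geom$brain])
      sc <- cfg@lagRangeNormal[1] +
        (base - rng[1]) / (rng[2] - rng[1]) * diff(cfg@lagRangeNormal)
      if (maxAdjacentDiff(sc, geom$brain & !les$lesion) <= cfg@maxGradient) break
      base <- smoothVolume(base, rep(1.5, 3))
    }
    # guarantee the bound: contract the field about its midpoint if needed
    worst <- maxAdjacentDiff(sc, geom$brain & !les$lesion)
    if (worst > cfg@maxGradient) {
      mid <- mean(cfg@lagRangeNormal)
      sc <- mid + (sc - mid) * (cfg@maxGradient / worst)
    }
    lagField[geom$brain] <- sc[geom$brain]
    lesBase <- smoothField(d, 2)
    rngL <- range(lesBase[les$lesion])
    lesVals <- cfg@lagRangeLesion[1] +
      (lesBase - rngL[1]) / max(rngL[2] - rngL[1], 1e-12) * diff(cfg@lagRangeLesion)
    lagField[les$lesion] <- lesVals[les$lesion]
    lagField[geom$sinus] <- 0

    amp <- array(1, d) + 0.25 * smoothField(d, 2)
    amp <- pmin(pmax(amp, 0.3), 2)
    amp[geom$sinus] <- 1.5

    # extended source so that cropped, delayed copies never wrap
    pad <- ceiling(22 / tr)
    nExt <- nT + 2L * pad
    slfoExt <- generateSLFO(nExt, tr, cfg@slfoBand, seed = deriveSeed(cfg@seed, 1L))
    keep <- (pad + 1L):(pad + nT)

    active <- geom$brain | geom$sinus
    idx <- which(active)
    # quantize lags finely so identical delays share one phase-ramp FFT
    q <- round(lagField[idx] / 0.005) * 0.005
    lagField[idx] <- q
    uq <- sort(unique(q))
    delayed <- delaySignal(slfoExt, uq, tr)[keep, , drop = FALSE]

    data <- array(stats::rnorm(prod(d) * nT, sd = 1 / cfg@snr), c(d, nT))
    dataMat <- matrix(data, prod(d), nT)
    dataMat[idx, ] <- dataMat[idx, ] +
      amp[idx] * t(delayed[, match(q, uq), drop = FALSE])

    # smooth motion excursions; rotations scaled to comparable arc length
    trans <- matrix(0, nT, 3)
    rot <- matrix(0, nT, 3)
    if (cfg@motionAmplitude > 0) {
      for (j in 1:3) {
        w <- stats::filter(stats::rnorm(nT), rep(1 / 25, 25), sides = 2)
        w[is.na(w)] <- 0
        w <- w - w[1]
        trans[, j] <- w / max(abs(w), 1e-12) * cfg@motionAmplitude
        w2 <- stats::filter(stats::rnorm(nT), rep(1 / 25, 25), sides = 2)
        w2[is.na(w2)] <- 0
        w2 <- w2 - w2[1]
        rot[, j] <- w2 / max(abs(w2), 1e-12) * cfg@motionAmplitude / 50
      }
      # motion-coupled artifact: standardized parameters times smooth loadings
      M <- cbind(trans, rot)
      for (j in 1:6) {
        mj <- M[, j]
        if (stats::sd(mj) < 1e-12) next
        loading <- smoothField(d, 2) * 0.3 * cfg@motionAmplitude
        dataMat <- dataMat + outer(as.vector(loading), as.vector(scale(mj))[seq_len(nT)])
      }
    }

    bold <- BoldSeries(array(dataMat, c(d, nT)), voxelSize = cfg@voxelSize,
                       tr = tr, brainMask = geom$brain)
    truth <- new("GroundTruth", lagField = lagField,
                 lesionMask = array(les$lesion, d),
                 sinusMask = array(geom$sinus, d),
                 territoryAtlas = geom$atlas,
                 dwiMask = array(les$dwi, d),
                 slfoSignal = slfoExt[keep],
                 amplitudeField = amp)
    motion <- MotionTrace(trans, rot, tr)
    list(bold = bold, truth = truth, motion = motion)
  })
}

# Largest |lag difference| over 6-adjacent voxel pairs inside `mask`.
maxAdjacentDiff <- function(field, mask) {
  d <- dim(field)
  mx <- 0
  for (ax in 1:3) {
    i1 <- lapply(d, seq_len); i2 <- i1
    i1[[ax]] <- seq_len(d[ax] - 1L); i2[[ax]] <- 2:d[ax]
    a <- do.call(`[`, c(list(field), i1)); b <- do.call(`[`, c(list(field), i2))
    ma <- do.call(`[`, c(list(mask), i1)) & do.call(`[`, c(list(mask), i2))
    if (any(ma)) mx <- max(mx, max(abs(a - b)[ma]))
  }
  mx
}

#' Generate a cohort of synthetic subjects on disk
#'
#' Writes one directory per subject containing the 4D BOLD NIfTI, the
#' masks (brain, sinus, lesion, DWI core), the territory atlas, the true
#' lag field, the motion TSV and a truth sidecar JSON, plus a cohort-level
#' manifest JSON listing paths and derived seeds. Re-running with the same
#' configuration and master seed reproduces identical files.
#'
#' @param cfg a [SyntheticConfig-class] used as a template; each subject
#'   gets a seed derived from `seed`.
#' @param nSubjects number of subjects (>= 1).
#' @param outputDir directory to create.
#' @param seed master seed; defaults to `cfg@seed`.
#' @return (invisibly) the manifest as a list.
#' @export
generateCohort <- function(cfg, nSubjects, outputDir, seed = cfg@seed) {
  stopifnot(nSubjects >= 1L)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outputDir)) stop("cannot create output directory: ", outputDir)
  entries <- vector("list", nSubjects)
  for (i in seq_len(nSubjects)) {
    subSeed <- deriveSeed(seed, i, stream = 10L)
    subCfg <- cfg
    subCfg@seed <- subSeed
    sub <- generateSubject(subCfg)
    sdir <- file.path(outputDir, sprintf("sub-%03d", i))
    dir.create(sdir, showWarnings = FALSE)
    writeSubjectBundle(sub, sdir)
    entries[[i]] <- list(id = sprintf("sub-%03d", i), seed = subSeed,
                         dir = sprintf("sub-%03d", i))
  }
  manifest <- list(nSubjects = nSubjects, masterSeed = seed,
                   configHash = configHash(cfg), subjects = entries)
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
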