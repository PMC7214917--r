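# Shared fixtures, all generated in code at test time.

# Desk-scale generator configuration for fast end-to-end tests.
tinyConfig <- function(seed = 1L, snr = 1e6, nFrames = 300L,
                       lesionFraction = 0.12, ...) {
  syntheticConfig(gridShape = c(12L, 12L, 6L), voxelSize = c(3, 3, 4),
                  nFrames = nFrames, snr = snr,
                  lesionFraction = lesionFraction, seed = seed, ...)
}

# A toy BoldSeries with arbitrary content.
toyBold <- function(dims = c(4, 4, 2), nFrames = 50, tr = 0.4, seed = 1) {
  withr::with_seed(seed,
    BoldSeries(array(rnorm(prod(dims) * nFrames), c(dims, nFrames)),
               voxelSize = c(3, 3, 4), tr = tr))
}

# Band-limited noise series (the class of signal the pipeline filters to).
bandNoise <- function(n, tr = 0.4, seed = 1) {
  generateSLFO(n, tr, c(0.01, 0.15), seed = seed)
}

# Independent brute-force lag oracle: plain cor() at every integer shift,
# visiting shifts by ascending |lag| with a strict > update (the stated
# tie-break), entirely separate from the production code path.
bruteForceLag <- function(x, ref, D, tr) {
  lags <- (-D):D
  ord <- order(abs(lags), lags)
  bestR <- -Inf; bestLag <- NA_real_
  Tn <- length(x)
  for (d in lags[ord]) {
    if (d >= 0) r <- suppressWarnings(cor(x[(1 + d):Tn], ref[1:(Tn - d)]))
    else r <- suppressWarnings(cor(x[1:(Tn + d)], ref[(1 - d):Tn]))
    if (!is.na(r) && r > bestR) { bestR <- r; bestLag <- d }
  }
  list(lag = bestLag * tr, r = bestR)
}

# A two-territory atlas on a small grid, split along x.
splitAtlas <- function(dims = c(10L, 10L, 4L)) {
  lab <- array(0L, dims)
  lab[1:(dims[1] %/% 2), , ] <- 1L
  lab[(dims[1] %/% 2 + 1):dims[1], , ] <- 2L
  TerritoryAtlas(lab)
}
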