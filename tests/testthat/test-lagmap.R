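test_that("reference extraction averages exactly the masked voxels", {
  n <- 40
  dat <- array(0, c(3, 1, 1, n))
  s1 <- bandNoise(n, seed = 1)
  dat[1, 1, 1, ] <- s1
  dat[2, 1, 1, ] <- -s1
  dat[3, 1, 1, ] <- s1
  bs <- BoldSeries(dat, c(3, 3, 4), 0.4)
  m <- function(...) array(c(...), c(3, 1, 1))
  one <- extractReference(bs, m(TRUE, FALSE, FALSE))
  expect_equal(one@values, s1, ignore_attr = TRUE)
  expect_identical(one@sourceMaskSize, 1L)
  opp <- extractReference(bs, m(TRUE, TRUE, FALSE))
  expect_true(all(abs(opp@values) < 1e-12))
  same <- extractReference(bs, m(TRUE, FALSE, TRUE))
  expect_equal(same@values, s1, ignore_attr = TRUE)
  expect_error(extractReference(bs, m(FALSE, FALSE, FALSE)), "empty")
})

test_that("lag estimation recovers exact shifts and correlation invariances", {
  n <- 825
  refv <- bandNoise(n, seed = 2)
  ref <- new("ReferenceSeries", values = refv, tr = 0.4, sourceMaskSize = 5L)
  self <- estimateLag(refv, ref, maxLag = 20)
  expect_identical(self$lag, 0)
  expect_equal(self$r, 1)
  shifted <- c(rep(0, 10), refv[1:(n - 10)])
  del <- estimateLag(shifted, ref, maxLag = 20)
  expect_equal(del$lag, 4)         # 10 samples x 0.4 s
  expect_gt(del$r, 0.99)
  aff <- estimateLag(3 * refv + 5, ref, maxLag = 20)
  expect_identical(aff$lag, self$lag)
  expect_equal(aff$r, self$r, tolerance = 1e-12)
  flat <- estimateLag(rep(1, n), ref, maxLag = 20)
  expect_true(is.na(flat$lag) && is.na(flat$r))  # flagged, not an error
})

test_that("production lag estimates equal the brute-force oracle", {
  tr <- 0.4
  n <- 200
  D <- 12L
  for (i in 1:40) {
    x <- bandNoise(n, seed = 100 + i)
    y <- bandNoise(n, seed = 500 + i)
    ref <- new("ReferenceSeries", values = y, tr = tr, sourceMaskSize = 1L)
    prod <- estimateLag(x, ref, maxLag = D * tr)
    bf <- bruteForceLag(x, y, D, tr)
    expect_identical(prod$lag, bf$lag)
    expect_equal(prod$r, bf$r, tolerance = 1e-12)
  }
})

test_that("lag estimation is antisymmetric in its arguments", {
  tr <- 0.4
  for (i in 1:15) {
    a <- bandNoise(180, seed = 40 + i)
    b <- bandNoise(180, seed = 70 + i)
    expect_identical(estimateLag(a, b, 6, tr = tr)$lag,
                     -estimateLag(b, a, 6, tr = tr)$lag)
  }
})

test_that("null calibration is seeded and its threshold is the quantile", {
  refv <- bandNoise(300, seed = 3)
  ref <- new("ReferenceSeries", values = refv, tr = 0.4, sourceMaskSize = 5L)
  c1 <- calibrateNull(ref, maxLag = 8, nNull = 150, alpha = 0.5, seed = 9)
  c2 <- calibrateNull(ref, maxLag = 8, nNull = 150, alpha = 0.5, seed = 9)
  expect_identical(c1@nullMaxR, c2@nullMaxR)
  expect_equal(rThreshold(c1), median(c1@nullMaxR))
  c3 <- calibrateNull(ref, maxLag = 8, nNull = 150, alpha = 0.05, seed = 9)
  expect_identical(c1@nullMaxR, c3@nullMaxR)  # same surrogates, new quantile
  expect_gt(rThreshold(c3), rThreshold(c1))
  expect_error(calibrateNull(ref, nNull = 50), ">= 100")
})

test_that("phase randomization preserves the amplitude spectrum", {
  x <- bandNoise(256, seed = 5)
  s <- phaseRandomize(x, 4, seed = 11)
  for (i in 1:4)
    expect_equal(Mod(fft(s[i, ])), Mod(fft(x)), tolerance = 1e-8)
  expect_identical(phaseRandomize(x, 4, seed = 11), s)
})

test_that("lag maps recover the truth on a noise-free subject", {
  sub <- generateSubject(tinyConfig(seed = 12, snr = 1e9))
  # without spatial smoothing the only error is TR quantization: <= tr/2
  pp <- preprocessBold(sub$bold, sub$motion, nDiscard = 10L, fwhm = 0)
  ref <- extractReference(pp$series, sub$truth@sinusMask)
  calib <- calibrateNull(ref, maxLag = 15, nNull = 120, alpha = 0.05, seed = 2)
  lm <- mapLags(pp$series, ref, calib, maxLag = 15)
  brain <- sub$bold@brainMask
  expect_true(all(validMask(lm)[brain]))          # valid everywhere in brain
  expect_false(any(validMask(lm)[!brain]))        # and only in brain
  err <- abs(lagValues(lm)[brain] - sub$truth@lagField[brain])
  expect_lte(median(err), 0.2)                    # within tr/2 at the median
  rng <- lagValues(lm)[brain]
  expect_true(all(rng >= -15 & rng <= 15))        # within tracking range

  # the standard smoothed path blends lags near the lesion edge but stays
  # within one TR at the median
  pps <- preprocessBold(sub$bold, sub$motion, nDiscard = 10L, fwhm = 6)
  refs <- extractReference(pps$series, sub$truth@sinusMask)
  lms <- mapLags(pps$series, refs, calib, maxLag = 15)
  errS <- abs(lagValues(lms)[brain] - sub$truth@lagField[brain])
  expect_lte(median(errS), 0.4)
})

test_that("a voxel holding the reference itself maps to lag 0 and valid", {
  n <- 400
  refv <- bandNoise(n, seed = 21)
  dat <- array(rnorm(8 * n, sd = 0.1), c(2, 2, 2, n))
  dat[1, 1, 1, ] <- refv
  bs <- BoldSeries(dat, c(3, 3, 4), 0.4)
  sinus <- array(FALSE, c(2, 2, 2)); sinus[1, 1, 1] <- TRUE
  ref <- extractReference(bs, sinus)
  calib <- calibrateNull(ref, maxLag = 8, nNull = 120, alpha = 0.05, seed = 3)
  lm <- mapLags(bs, ref, calib, maxLag = 8)
  expect_identical(lm@lags[1, 1, 1], 0)
  expect_true(lm@valid[1, 1, 1])
})

test_that("voxels drawn from the null model pass at about the alpha rate", {
  n <- 400
  refv <- bandNoise(n, seed = 31)
  ref <- new("ReferenceSeries", values = refv, tr = 0.4, sourceMaskSize = 5L)
  calib <- calibrateNull(ref, maxLag = 10, nNull = 400, alpha = 0.05, seed = 41)
  probes <- phaseRandomize(refv, 600, seed = 51)
  r <- vapply(seq_len(nrow(probes)),
              function(i) estimateLag(probes[i, ], ref, maxLag = 10)$r,
              numeric(1))
  rate <- mean(r >= rThreshold(calib))
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})
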