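test_that("initial-frame discard follows the 850 -> 825 accounting", {
  s <- toyBold(c(2, 2, 2), nFrames = 850)
  out <- discardInitial(s, 25)
  expect_identical(nFrames(out), 825L)
  expect_equal(out@data[, , , 1], s@data[, , , 26])
  expect_identical(discardInitial(s, 0), s)
  short <- toyBold(c(2, 2, 2), nFrames = 10)
  expect_error(discardInitial(short, 10), "at least one frame")
})

test_that("scan segments reproduce the nominal durations and frame counts", {
  s <- toyBold(c(2, 2, 2), nFrames = 850, tr = 0.4)
  post <- discardInitial(s, 25)
  segs <- makeSegments(post, c(0.2, 0.4, 0.6, 0.8, 1.0), nOriginal = 850)
  expect_equal(vapply(segs, `[[`, numeric(1), "duration"),
               c("0.2" = 68, "0.4" = 136, "0.6" = 204, "0.8" = 272, "1" = 340))
  expect_identical(segs[["0.6"]]$nFramesSegment, 485L) # round(0.6*850) - 25
  expect_identical(segs[["0.2"]]$nFramesSegment, 145L) # round(0.2*850) - 25
  expect_identical(segs[["1"]]$nFramesSegment, 825L)
  expect_identical(nFrames(segs[["1"]]$series), 825L)
  # prefix property: the 0.2 segment is the first frames of the series
  expect_equal(segs[["0.2"]]$series@data,
               post@data[, , , 1:segs[["0.2"]]$nFramesSegment, drop = FALSE])
  expect_error(makeSegments(post, 0.001, nOriginal = 850), "fewer than 2")
})

test_that("confound regression yields residuals orthogonal to the design", {
  n <- 120
  conf <- cbind(sin(seq_len(n) / 7), cos(seq_len(n) / 13))
  sig <- bandNoise(n, seed = 4)
  sig <- residuals(lm(sig ~ conf))           # orthogonal target signal
  dims <- c(3, 1, 1)
  dat <- array(0, c(dims, n))
  dat[1, 1, 1, ] <- conf[, 1]                # pure confound
  dat[2, 1, 1, ] <- sig + 2 * conf[, 2]      # signal + confound
  dat[3, 1, 1, ] <- 5                        # constant
  s <- BoldSeries(dat, c(3, 3, 4), 0.4)
  out <- regressConfounds(s, conf)
  expect_lt(max(abs(out@data[1, 1, 1, ])), 1e-8)
  expect_equal(out@data[2, 1, 1, ], sig, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(max(abs(out@data[3, 1, 1, ])), 1e-8) # intercept removes mean
  res <- matrix(out@data, prod(dims), n)
  for (j in 1:2)
    expect_lt(abs(sum(res[2, ] * conf[, j])) /
                (sqrt(sum(res[2, ]^2)) * sqrt(sum(conf[, j]^2))), 1e-6)
  # all-zero confounds reduce to demeaning
  out0 <- regressConfounds(s, matrix(0, n, 2))
  expect_equal(out0@data[2, 1, 1, ],
               dat[2, 1, 1, ] - mean(dat[2, 1, 1, ]), tolerance = 1e-10,
               ignore_attr = TRUE)
  # collinear columns are dropped with a warning
  expect_warning(regressConfounds(s, cbind(conf, conf[, 1])), "collinear")
})

test_that("spatial smoothing preserves constants, sums and the impulse peak", {
  dims <- c(15, 15, 9)
  s <- BoldSeries(array(1, c(dims, 2)), c(3, 3, 3), 0.4)
  expect_identical(smoothSpatial(s, 0), s)
  sm <- smoothSpatial(s, 6)
  expect_equal(sm@data[8, 8, 5, 1], 1, tolerance = 1e-6) # flat stays flat
  imp <- array(0, c(dims, 1))
  imp[8, 8, 5, 1] <- 1
  si <- smoothSpatial(BoldSeries(imp, c(3, 3, 3), 0.4), 6)
  expect_equal(sum(si@data), 1, tolerance = 1e-3)        # mass preserved
  # closed-form peak: product of normalized discrete Gaussian centre
  # weights at sigma = 6 / 2.3548 / 3 = 0.849 voxels per axis
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 3
  k <- exp(-((-4):4)^2 / (2 * sigma^2)); k <- k / sum(k)
  expect_equal(si@data[8, 8, 5, 1], k[5]^3, tolerance = 1e-10)
  expect_equal(k[5]^3, dnorm(0, sd = sigma)^3, tolerance = 2e-3)
})

test_that("band-pass is zero-phase, passes the band and rejects out-of-band", {
  tr <- 0.4
  n <- 825
  t <- (seq_len(n) - 1) * tr
  mid <- 150:675
  tone <- function(f) sin(2 * pi * f * t)
  mk <- function(v) BoldSeries(array(v, c(1, 1, 1, n)), c(3, 3, 4), tr)
  inb <- bandPass(mk(tone(0.05)), 0.01, 0.15)@data[1, 1, 1, ]
  expect_gte(max(abs(inb[mid])), 0.9)
  # no phase shift: peak cross-correlation of input vs output at lag 0
  cc <- ccf(tone(0.05)[mid], inb[mid], lag.max = 20, plot = FALSE)
  expect_equal(as.numeric(cc$lag)[which.max(cc$acf)], 0)
  oob <- bandPass(mk(tone(0.5)), 0.01, 0.15)@data[1, 1, 1, ]
  # steady state, away from the slowly decaying low-cutoff edge transient
  expect_lte(max(abs(oob[250:575])), 0.1)
  dc <- bandPass(mk(rep(3, n)), 0.01, 0.15)@data[1, 1, 1, ]
  expect_lt(max(abs(dc)), 1e-8)
  expect_error(bandPass(mk(tone(0.05)), 0.15, 0.01), "Nyquist")
})

test_that("band-pass does not shift the correlation peak of a delayed pair", {
  tr <- 0.4
  n <- 600
  src <- bandNoise(n + 50, seed = 8)
  a <- src[16:(n + 15)]
  b <- src[26:(n + 25)]            # a[t] = b[t - 10]: a lags b by 10 samples
  mk <- function(v) BoldSeries(array(v, c(1, 1, 1, n)), c(3, 3, 4), tr)
  fa <- bandPass(mk(a), 0.01, 0.15)@data[1, 1, 1, ]
  fb <- bandPass(mk(b), 0.01, 0.15)@data[1, 1, 1, ]
  before <- bruteForceLag(a, b, 25L, tr)
  after <- bruteForceLag(fa, fb, 25L, tr)
  expect_equal(before$lag, 4)
  expect_equal(after$lag, before$lag)
})

test_that("framewise displacement matches its hand-computed examples", {
  n <- 10
  tr0 <- matrix(0, n, 3)
  mt <- MotionTrace(tr0, tr0, 0.4)
  fd0 <- framewiseDisplacement(mt)
  expect_true(all(fd0$fd[-1] == 0))
  expect_identical(fd0$meanFD, 0)

  tr1 <- tr0; tr1[6:n, ] <- rep(c(0.1, 0.2, 0.3), each = n - 5)
  fd1 <- framewiseDisplacement(MotionTrace(tr1, tr0, 0.4))
  expect_equal(fd1$fd[6], 0.6)                  # |0.1|+|0.2|+|0.3|
  expect_true(all(fd1$fd[c(2:5, 7:n)] == 0))

  rot <- tr0; rot[4:n, 1] <- 0.01
  fd2 <- framewiseDisplacement(MotionTrace(tr0, rot, 0.4), headRadius = 50)
  expect_equal(fd2$fd[4], 0.5)                  # 50 mm x 0.01 rad
  expect_equal(fd2$meanFDx10, 10 * fd2$meanFD)
  expect_error(framewiseDisplacement(MotionTrace(tr0[1, , drop = FALSE],
                                                 tr0[1, , drop = FALSE], 0.4)),
               "at least 2")
})

test_that("DVARS matches its hand-computed example and is homogeneous", {
  dat <- array(0, c(2, 1, 1, 3))
  dat[1, 1, 1, ] <- c(0, 3, 3)
  dat[2, 1, 1, ] <- c(0, 4, 4)
  s <- BoldSeries(dat, c(3, 3, 4), 0.4)
  dv <- dvars(s)
  expect_true(is.na(dv$dvars[1]))
  expect_equal(dv$dvars[2], sqrt((9 + 16) / 2))  # ~3.536
  expect_equal(dv$dvars[3], 0)
  s2 <- BoldSeries(2 * dat, c(3, 3, 4), 0.4)
  expect_equal(dvars(s2)$dvars[-1], 2 * dv$dvars[-1])
  const <- BoldSeries(array(7, c(2, 1, 1, 5)), c(3, 3, 4), 0.4)
  expect_true(all(dvars(const)$dvars[-1] == 0))
  empty <- BoldSeries(dat, c(3, 3, 4), 0.4, brainMask = array(FALSE, c(2, 1, 1)))
  expect_error(dvars(empty), "empty")
})

test_that("motion-free noise-free data yield FD and DVARS of exactly zero", {
  sub <- generateSubject(tinyConfig(seed = 6, snr = 1e12, motionAmplitude = 0))
  fd <- framewiseDisplacement(sub$motion)
  expect_true(all(fd$fd[-1] == 0))
  # after confound regression the sLFO remains, so DVARS is not zero;
  # the motion-free claim is about motion metrics on static content:
  static <- BoldSeries(array(rep(sub$bold@data[, , , 1], 4),
                             c(dim(sub$bold@data)[1:3], 4)),
                       sub$bold@voxelSize, sub$bold@tr, sub$bold@brainMask)
  expect_true(all(dvars(static)$dvars[-1] == 0))
})
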