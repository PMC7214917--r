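test_that("affected territory follows the DWI-overlap fraction rule", {
  atlas <- splitAtlas(c(10L, 10L, 4L))   # label 1: x 1-5, label 2: x 6-10
  dm <- dim(atlas@labels)
  mk <- function(ix) { m <- array(FALSE, dm); m[ix] <- TRUE; m }

  inside <- array(FALSE, dm); inside[2:3, 2:3, 2] <- TRUE
  expect_identical(affectedTerritory(atlas, inside), 1L)

  # 60/40 split across the x = 5/6 border
  split <- array(FALSE, dm)
  split[4:5, 1:6, 1] <- TRUE   # 12 voxels in label 1
  split[6, 1:8, 1] <- TRUE     #  8 voxels in label 2
  expect_identical(affectedTerritory(atlas, split), c(1L, 2L))

  # 2% spillover stays below the default 5% minimum fraction
  spill <- array(FALSE, dm)
  spill[1:5, 1:10, 1:2] <- TRUE          # 100 voxels in label 1
  spill[6, 1, 3] <- TRUE; spill[6, 2, 3] <- TRUE  # 2 voxels in label 2
  expect_identical(affectedTerritory(atlas, spill), 1L)
  expect_identical(affectedTerritory(atlas, spill, minFraction = 0.01),
                   c(1L, 2L))

  expect_error(affectedTerritory(atlas, array(FALSE, dm)), "empty")
  outside <- array(FALSE, dm)
  atlas0 <- TerritoryAtlas({ l <- atlas@labels; l[1, 1, 1] <- 0L; l })
  outside[1, 1, 1] <- TRUE
  expect_error(affectedTerritory(atlas0, outside), "outside the atlas")
})

test_that("delineation restricts to territory, filters clusters, nests", {
  dm <- c(10L, 10L, 4L)
  atlas <- splitAtlas(dm)
  vs <- c(3, 3, 4) # voxel volume 36 mm^3 = 0.036 mL
  vals <- array(0, dm)
  vals[2:3, 2:6, 1:2] <- 5      # 20-voxel cluster inside label 1
  vals[8:9, 8:9, 3] <- 5        # 4-voxel cluster inside label 2
  del <- delineateLesion(vals, 2.3, 1L, atlas, minClusterML = 0, voxelSize = vs)
  expect_identical(sum(del@lesionMask), 20L)           # outside cluster dropped
  expect_true(all(atlas@labels[del@lesionMask] == 1L))
  expect_equal(volumeML(del), 20 * 36 / 1000)
  expect_identical(del@mapKind, "tmax")

  # cluster-size filter: the 4-voxel cluster is 0.144 mL
  both <- delineateLesion(vals, 2.3, c(1L, 2L), atlas,
                          minClusterML = 0, voxelSize = vs)
  expect_identical(sum(both@lesionMask), 24L)
  filt <- delineateLesion(vals, 2.3, c(1L, 2L), atlas,
                          minClusterML = 0.2, voxelSize = vs)
  expect_identical(sum(filt@lesionMask), 20L)
  expect_identical(filt@nClusters, 1L)

  # strict inequality and the legal empty result
  low <- delineateLesion(array(2.3, dm), 2.3, c(1L, 2L), atlas,
                         minClusterML = 0, voxelSize = vs)
  expect_identical(sum(low@lesionMask), 0L)
  expect_identical(volumeML(low), 0)

  # nesting across the delay thresholds
  field <- array(runif(prod(dm), -1, 8), dm)
  m0 <- delineateLesion(field, 0, c(1L, 2L), atlas, 0, vs)@lesionMask
  m23 <- delineateLesion(field, 2.3, c(1L, 2L), atlas, 0, vs)@lesionMask
  m46 <- delineateLesion(field, 4.6, c(1L, 2L), atlas, 0, vs)@lesionMask
  expect_true(all(m46 <= m23))
  expect_true(all(m23 <= m0))
})

test_that("delineating a 0/1 delineation output at 0.5 is idempotent", {
  dm <- c(10L, 10L, 4L)
  atlas <- splitAtlas(dm)
  field <- array(rnorm(prod(dm), 1, 2), dm)
  d1 <- delineateLesion(field, 2, c(1L, 2L), atlas, 0, c(1, 1, 1))
  d2 <- delineateLesion(array(as.numeric(d1@lesionMask), dm), 0.5,
                        c(1L, 2L), atlas, 0, c(1, 1, 1))
  expect_identical(d2@lesionMask, d1@lesionMask)
})

test_that("LagMap delineation uses only significant voxels", {
  dm <- c(6L, 6L, 2L)
  atlas <- TerritoryAtlas(array(1L, dm))
  lags <- array(5, dm)
  valid <- array(TRUE, dm); valid[1:3, , ] <- FALSE
  lm <- new("LagMap", lags = lags, peakR = array(0.9, dm), valid = valid,
            tr = 0.4, trackingRange = c(-20, 20), voxelSize = c(1, 1, 1))
  del <- delineateLesion(lm, 2.3, 1L, atlas, minClusterML = 0)
  expect_identical(del@lesionMask, valid)
  expect_identical(del@mapKind, "bold_delay")
  all36 <- delineateLesion(lm, 2.3, 1L, atlas, minClusterML = 0,
                           useValidOnly = FALSE)
  expect_identical(sum(all36@lesionMask), as.integer(prod(dm)))
})

test_that("noise-free truth-field delineation recovers the lesion", {
  for (sd in c(1, 2, 3)) {
    sub <- generateSubject(tinyConfig(seed = sd))
    truth <- sub$truth
    aff <- affectedTerritory(truth@territoryAtlas, truth@dwiMask)
    del <- delineateLesion(truth@lagField, 2.3, aff, truth@territoryAtlas,
                           minClusterML = 0, voxelSize = c(3, 3, 4))
    expect_gte(computeDice(del@lesionMask, truth@lesionMask), 0.95)
  }
})

test_that("lesion volume is count times voxel volume", {
  expect_identical(lesionVolume(array(FALSE, c(4, 4, 4)), c(1, 1, 1)), 0)
  expect_equal(lesionVolume(array(TRUE, c(10, 10, 10)), c(1, 1, 1)), 1)
  m <- array(FALSE, c(10, 10, 10)); m[1:100] <- TRUE
  expect_equal(lesionVolume(m, c(3, 3, 4)), 3.6)
})

test_that("connected components respect the chosen connectivity", {
  m <- array(FALSE, c(4, 4, 1))
  m[1, 1, 1] <- TRUE; m[2, 2, 1] <- TRUE  # diagonal contact
  expect_identical(max(labelComponents(m, 26L)), 1L)
  expect_identical(max(labelComponents(m, 6L)), 2L)
})
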