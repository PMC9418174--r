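# volumetry: voxel-count volumes, trajectories, onset detection

test_that("mask volume is voxel count times voxel volume", {
  m <- array(0L, c(10, 10, 10)); m[3:7, 3:7, 3:7] <- 1L
  rec <- maskVolume(m, 1, spacing = c(0.22, 0.24, 0.25))
  expect_identical(rec$nVoxels, 125L)
  expect_equal(rec$volumeMm3, 125 * 0.0132)
  expect_false(rec$truncated)
  # absent label -> zero-volume record, no error
  zero <- maskVolume(m, 9, spacing = c(1, 1, 1))
  expect_identical(zero$nVoxels, 0L)
  expect_equal(zero$volumeMm3, 0)
  expect_error(maskVolume(m, 1, spacing = c(0, 1, 1)), "spacing")
})

test_that("grid-aligned box phantom volume is exact and boundary flags work", {
  ph <- simulatePhantom(
    list(phantomShape(1, "box", c(2.2, 2.4, 2.5) / 2, c(2.2, 2.4, 2.5))),
    gridShape = c(20, 20, 20), spacing = c(0.22, 0.24, 0.25))
  rec <- maskVolume(ph$mask, 1)
  expect_equal(rec$volumeMm3, ph$truth$analyticVolumeMm3)
  expect_true(rec$truncated)  # box starts at the grid corner
  inner <- simulatePhantom(
    list(phantomShape(1, "box", c(2.2, 2.4, 2.5), c(2.2, 2.4, 2.5))),
    gridShape = c(20, 20, 20), spacing = c(0.22, 0.24, 0.25))
  expect_false(maskVolume(inner$mask, 1)$truncated)
  expect_equal(maskVolume(inner$mask, 1)$volumeMm3, 13.2)
})

test_that("splitting one label into two conserves total volume exactly", {
  ph <- simulatePhantom(list(phantomShape(1, "ellipsoid", c(4, 4, 4),
                                          c(2.5, 2, 1.5))),
                        gridShape = c(40, 40, 40), spacing = rep(0.2, 3))
  whole <- maskVolume(ph$mask, 1)$volumeMm3
  arr <- voxelData(ph$mask)
  split <- arr
  split[arr == 1L & slice.index(arr, 3) > 20] <- 2L
  v1 <- maskVolume(split, 1, spacing = rep(0.2, 3))$volumeMm3
  v2 <- maskVolume(split, 2, spacing = rep(0.2, 3))$volumeMm3
  expect_identical(v1 + v2, whole)
})

test_that("ellipsoid voxelisation error shrinks with refinement", {
  errs <- vapply(c(0.4, 0.2, 0.1), function(sp) {
    n <- round(8 / sp)
    ph <- simulatePhantom(list(phantomShape(1, "ellipsoid", c(4, 4, 4),
                                            c(3, 3, 3))),
                          gridShape = rep(n, 3), spacing = rep(sp, 3))
    abs(ph$truth$nVoxels * sp^3 - ph$truth$analyticVolumeMm3) /
      ph$truth$analyticVolumeMm3
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("volume trajectories report percent change and onset flags", {
  tr <- volumeTrajectory(c(100, 145), c(10, 12))
  expect_equal(tr$pctChange, c(NA, 45))
  flat <- volumeTrajectory(c(80, 80, 80), c(2, 4, 6))
  expect_equal(flat$pctChange[-1], c(0, 0))
  onset <- volumeTrajectory(c(0, 0, 0.5, 97, 259), c(4, 6, 8, 10, 12))
  expect_identical(onset$flag, c("", "", "onset", "", ""))
  expect_true(is.na(onset$pctChange[3]))
  expect_equal(onset$pctChange[4], 100 * (97 - 0.5) / 0.5)
  expect_error(volumeTrajectory(c(1, 2), c(4, 4)), "duplicate")
  # percent changes are invariant to a global volume rescaling
  k <- 0.37
  expect_equal(volumeTrajectory(k * c(100, 145, 90), c(1, 2, 3))$pctChange,
               volumeTrajectory(c(100, 145, 90), c(1, 2, 3))$pctChange)
})

test_that("onset detection finds the first threshold crossing", {
  rec <- data.frame(animal = "f3", organ = "mammary",
                    timepoint = c(4, 6, 8, 10, 12),
                    volumeMm3 = c(0, 0, 0.5, 97, 259))
  on <- detectOnset(rec, threshold = 0.4)
  expect_equal(on$onsetTimepoint, 8)
  expect_equal(on$onsetVolumeMm3, 0.5)
  # never reaching the threshold -> omitted
  low <- data.frame(animal = "a", organ = "o", timepoint = 1:3,
                    volumeMm3 = c(0, 0.1, 0.2))
  expect_identical(nrow(detectOnset(low, 0.4)), 0L)
  first <- data.frame(animal = "a", organ = "o", timepoint = 1:3,
                      volumeMm3 = c(1.5, 2, 3))
  expect_equal(detectOnset(first, 0.1)$onsetTimepoint, 1)
  expect_error(detectOnset(rec, threshold = 0), "threshold")
})
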