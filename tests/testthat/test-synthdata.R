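# generators: signal models, noise behaviour, phantoms, slides, cohorts

test_that("IR generator evaluates the recovery model and its asymptote", {
  s <- simulateIRSeries(c(100, 600, 5000), a = 1000, b = 1800,
                        t1Star = 600, magnitude = FALSE)
  expect_equal(relaxSignals(s)[2], 1000 - 1800 * exp(-1), tolerance = 1e-12)
  expect_equal(relaxSignals(s)[3], 1000, tolerance = 1e-3)
  # t1 parameterisation routes through the Look-Locker relation
  s2 <- simulateIRSeries(c(600), a = 1000, b = 1800, t1 = 480,
                         magnitude = FALSE)
  expect_equal(relaxSignals(s2), 1000 - 1800 * exp(-1), tolerance = 1e-12)
})

test_that("decay generator evaluates the offset model and first-echo bias", {
  s <- simulateDecaySeries(c(14, 1000), m0 = 1000, t2 = 14, c0 = 50)
  expect_equal(relaxSignals(s)[1], 1000 * exp(-1) + 50, tolerance = 1e-12)
  expect_equal(relaxSignals(s)[2], 50, tolerance = 1e-6)
  sb <- simulateDecaySeries(c(6, 12), m0 = 1000, t2 = 14, c0 = 50,
                            firstEchoFactor = 0.8)
  expect_equal(relaxSignals(sb)[1], 0.8 * (1000 * exp(-6 / 14) + 50),
               tolerance = 1e-12)
  expect_equal(relaxSignals(sb)[2], 1000 * exp(-12 / 14) + 50,
               tolerance = 1e-12)
})

test_that("generator input validation names the violated rule", {
  expect_error(simulateIRSeries(numeric(0)), "empty")
  expect_error(simulateIRSeries(c(5, 3)), "increasing")
  expect_error(simulateIRSeries(c(0, 5)), "> 0")
  expect_error(simulateIRSeries(10, a = -1), "'a'")
  expect_error(simulateIRSeries(10, noiseSigma = -1), "noiseSigma")
  expect_error(simulateDecaySeries(10, t2 = -5), "'t2'")
})

test_that("generation is deterministic given the seed", {
  a <- simulateIRSeries(noiseSigma = 25, seed = 42)
  b <- simulateIRSeries(noiseSigma = 25, seed = 42)
  expect_identical(relaxSignals(a), relaxSignals(b))
  expect_false(identical(relaxSignals(a),
                         relaxSignals(simulateIRSeries(noiseSigma = 25,
                                                       seed = 43))))
})

test_that("Gaussian noise sd and Rician high-SNR mean match theory", {
  # Gaussian mode: sample sd converges to noiseSigma
  draws <- vapply(1:400, function(i)
    relaxSignals(simulateIRSeries(c(500), a = 1000, b = 1800, t1Star = 600,
                                  noiseSigma = 30, magnitude = FALSE,
                                  seed = i)), numeric(1))
  expect_lt(abs(sd(draws) - 30), 3 * 30 / sqrt(2 * 400))
  # Rician mode at high SNR: mean ~ sqrt(nu^2 + sigma^2)
  nu <- 1000 - 2000 * exp(-5000 / 500)
  draws <- vapply(1:1000, function(i)
    relaxSignals(simulateIRSeries(c(5000), a = 1000, b = 2000,
                                  t1Star = 500, noiseSigma = 20,
                                  seed = i)), numeric(1))
  expect_lt(abs(mean(draws) - sqrt(nu^2 + 20^2)), 3 * 20 / sqrt(1000))
  # magnitude mode never yields negative signals
  s <- simulateIRSeries(a = 100, b = 200, t1Star = 600, noiseSigma = 80,
                        seed = 9)
  expect_true(all(relaxSignals(s) >= 0))
})

test_that("grid-aligned box phantom labels exactly the expected voxels", {
  ph <- simulatePhantom(
    list(phantomShape(1, "box", c(1.1, 1.2, 1.25), c(2.2, 2.4, 2.5))),
    gridShape = c(20, 20, 20), spacing = c(0.22, 0.24, 0.25))
  expect_identical(ph$truth$nVoxels, 1000L)
  expect_equal(ph$truth$analyticVolumeMm3, 13.2)
  # empty shape list -> all-zero mask
  empty <- simulatePhantom(list(), gridShape = c(5, 5, 5),
                           spacing = c(1, 1, 1))
  expect_true(all(voxelData(empty$mask) == 0L))
  # duplicate labels are rejected
  expect_error(simulatePhantom(
    list(phantomShape(1, "box", c(2, 2, 2), c(1, 1, 1)),
         phantomShape(1, "box", c(4, 4, 4), c(1, 1, 1))),
    gridShape = c(10, 10, 10), spacing = c(0.5, 0.5, 0.5)), "duplicate")
})

test_that("voxelised ellipsoid volume approximates the analytic volume", {
  ph <- simulatePhantom(list(phantomShape(1, "ellipsoid", c(4, 4, 4),
                                          c(3, 3, 3))),
                        gridShape = c(80, 80, 80), spacing = rep(0.1, 3))
  vol <- ph$truth$nVoxels * 0.1^3
  expect_lt(abs(vol - 4 / 3 * pi * 27) / (4 / 3 * pi * 27), 0.02)
})

test_that("stain generator draws the exact positive count and colours", {
  sl <- simulateStainImage(500, 500, 0.18, seed = 1)
  expect_identical(sum(sl$truth), 45000L)
  none <- simulateStainImage(20, 20, 0, seed = 1)
  expect_false(any(none$truth))
  pure <- simulateStainImage(20, 20, 0.5, jitterSD = 0, seed = 1)
  px <- pixelData(pure$image)
  pos <- which(pure$truth)
  expect_true(all(px[, , 1][pos] == 0.20))
  expect_true(all(px[, , 3][pos] == 0.62))
  expect_error(simulateStainImage(10, 10, 0.5, jitterSD = 0,
                                  positiveColor = c(0.5, 0.5, 0.5),
                                  negativeColor = c(0.5, 0.5, 0.5)),
               "unlearnable")
})

test_that("cohort generator reproduces configured effects exactly at sd 0", {
  eff <- list(m1 = list(baseline = c(10, 20), genotype = -3, sex = 2,
                        sd = 0))
  coh <- simulateCohort(nPerGroup = 2, timepoints = c(4, 6), effects = eff,
                        tumorModel = NULL, seed = 1)
  r <- cohortData(coh)
  ctrlF <- r[r$genotype == "control" & r$sex == "f", ]
  expect_equal(ctrlF$value[order(ctrlF$timepoint)][c(1, 3)], c(10, 20))
  mutM <- r[r$genotype == "mutant" & r$sex == "m" & r$timepoint == 6, ]
  expect_equal(unique(mutM$value), 20 - 3 + 2)
})

test_that("cohort group means recover configured effects under noise", {
  eff <- list(t1 = list(baseline = rep(500, 2),
                        genotype = c(0, -160), sex = 0, sd = 15))
  coh <- simulateCohort(nPerGroup = 30, timepoints = c(10, 12),
                        effects = eff, tumorModel = NULL, seed = 7)
  r <- cohortData(coh)
  at12 <- r[r$timepoint == 12, ]
  d <- mean(at12$value[at12$genotype == "mutant"]) -
    mean(at12$value[at12$genotype == "control"])
  expect_lt(abs(d - (-160)), 3 * 15 / sqrt(60))
  at10 <- r[r$timepoint == 10, ]
  d10 <- mean(at10$value[at10$genotype == "mutant"]) -
    mean(at10$value[at10$genotype == "control"])
  expect_lt(abs(d10), 3 * 15 / sqrt(60))
})

test_that("tumor model controls onset and geometric growth", {
  none <- simulateCohort(nPerGroup = 3, seed = 2,
                         tumorModel = list(hazard = list(
                           mutant_f = rep(0, 6), mutant_m = rep(0, 6),
                           control_f = rep(0, 6), control_m = rep(0, 6)),
                           initialVolume = 0.5, growthFactor = 4))
  expect_false("tumor_volume" %in% cohortData(none)$measurement)
  all6 <- simulateCohort(nPerGroup = 2, timepoints = c(2, 4, 6),
                         effects = list(w = list(baseline = 1, genotype = 0,
                                                 sex = 0, sd = 0)),
                         tumorModel = list(hazard = list(
                           mutant_f = c(1, 0, 0), mutant_m = rep(0, 3),
                           control_f = rep(0, 3), control_m = rep(0, 3)),
                           initialVolume = 0.5, growthFactor = 4),
                         seed = 3)
  tum <- cohortData(all6)
  tum <- tum[tum$measurement == "tumor_volume", ]
  one <- tum[tum$animal == tum$animal[1], ]
  expect_equal(one$value[order(one$timepoint)], c(0.5, 2, 8))
})

test_that("cohort generator rejects unknown measurements and bad configs", {
  expect_error(simulateCohort(measurements = "nope", seed = 1), "unknown")
  expect_error(simulateCohort(nPerGroup = 1, seed = 1), "nPerGroup")
  expect_error(simulateCohort(timepoints = c(4, 2), seed = 1), "increasing")
  bad <- defaultCohortEffects()
  bad$body_weight$sd <- NULL
  expect_error(simulateCohort(effects = bad, seed = 1), "missing field")
})
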