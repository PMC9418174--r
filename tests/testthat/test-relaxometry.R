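# relaxometry: IRLS engine, T1/T2 model fits, ROI extraction, stability

test_that("noiseless Look-Locker fits recover the generating parameters", {
  f <- fitT1LookLocker(irSignedSeries(1000, 1800, 600))
  p <- fitParams(f)
  expect_equal(unname(p), c(1000, 1800, 600, 600 * (1800 / 1000 - 1)),
               tolerance = 1e-8)
  expect_true(isConverged(f))
  # ideal inversion b = 2a gives T1 = T1*
  f2 <- fitT1LookLocker(irSignedSeries(900, 1800, 750))
  expect_equal(t1Value(f2), 750, tolerance = 1e-6)
  # the Look-Locker correction holds exactly by construction
  expect_equal(f@t1, f@t1Star * (f@b / f@a - 1), tolerance = 1e-12)
})

test_that("polarity restoration recovers T1 from magnitude data", {
  s <- simulateIRSeries(seq(20, 2100, length.out = 40), a = 800, b = 1600,
                        t1Star = 700, magnitude = TRUE)
  f <- fitT1LookLocker(s)
  expect_lt(abs(t1Value(f) - 700) / 700, 1e-3)
  expect_gt(f@polarityFlipIndex, 0)
  # grid-search oracle agrees on the same magnitude instance after the
  # winning polarity restoration
  sig <- relaxSignals(s)
  sig[seq_len(f@polarityFlipIndex)] <- -sig[seq_len(f@polarityFlipIndex)]
  g <- gridFitT1(relaxTimes(s), sig)
  expect_lt(abs(t1Value(f) - g$t1) / g$t1, 1e-4)
})

test_that("T1 fit handles degenerate and invalid input as specified", {
  expect_error(fitT1LookLocker(RelaxationSeries(1:3, c(1, 2, 3))),
               "at least 4")
  flat <- RelaxationSeries(c(10, 20, 30, 40), rep(5, 4))
  f <- fitT1LookLocker(flat)
  expect_false(isConverged(f))
  expect_match(f@message, "unidentifiable")
  # b/a <= 1 (recovery from below, no inversion) is degenerate, not clamped
  dec <- simulateIRSeries(seq(50, 2000, length.out = 10), a = 1000, b = 500,
                          t1Star = 400, magnitude = FALSE)
  fd <- fitT1LookLocker(dec)
  expect_false(isConverged(fd))
  expect_match(fd@message, "b/a")
})

test_that("noiseless decay fits are exact and echo 1 is always excluded", {
  f <- fitT2MonoExp(decaySeries())
  expect_equal(unname(fitParams(f)), c(1000, 14, 50), tolerance = 1e-8)
  expect_identical(f@nPointsUsed, 13L)
  # arbitrary echo-1 corruption cannot change the fit
  base <- decaySeries()
  for (fac in c(0.8, 10)) {
    corrupted <- RelaxationSeries(relaxTimes(base),
                                  replace(relaxSignals(base), 1,
                                          relaxSignals(base)[1] * fac),
                                  kind = "echo_decay")
    expect_equal(fitParams(fitT2MonoExp(corrupted)), fitParams(f),
                 tolerance = 1e-10)
  }
  expect_error(fitT2MonoExp(RelaxationSeries(c(6, 12, 18), c(3, 2, 1),
                                             kind = "echo_decay")),
               "at least 3")
})

test_that("IRLS reduces to OLS with unit weights and respects maxIter = 0", {
  mod <- function(p, t) p[1] * exp(-t / p[2]) + p[3]
  t <- defaultTESchedule()
  set.seed(4)
  y <- mod(c(1000, 20, 30), t) + rnorm(length(t), 0, 15)
  unit <- irlsFit(mod, c(900, 15, 10), t, y, weightsRule = "unit")
  ref <- gridFitT2(t, y)
  expect_lt(abs(unit$par[2] - ref$par["t2"]) / ref$par["t2"], 5e-3)
  expect_true(all(unit$weights == 1))
  frozen <- irlsFit(mod, c(900, 15, 10), t, y, maxIter = 0)
  expect_identical(frozen$par, c(900, 15, 10))
  expect_false(frozen$converged)
  # zero-noise data: robust weights stay at 1 and the fit is exact
  clean <- irlsFit(mod, c(900, 15, 10), t, mod(c(1000, 20, 30), t))
  expect_true(all(clean$weights == 1))
  expect_equal(clean$par, c(1000, 20, 30), tolerance = 1e-6)
})

test_that("Huber IRLS resists a gross outlier better than OLS", {
  t <- defaultTESchedule()
  mod <- function(p, tt) p[1] * exp(-tt / p[2]) + p[3]
  set.seed(11)
  y <- mod(c(1000, 20, 30), t) + rnorm(length(t), 0, 10)
  y[6] <- y[6] * 10
  s <- RelaxationSeries(t, y, kind = "echo_decay")
  robust <- fitT2MonoExp(s)
  ols <- fitT2MonoExp(s, weightsRule = "unit")
  expect_lt(abs(t2Value(robust) - 20), abs(t2Value(ols) - 20))
  expect_lt(abs(t2Value(robust) - 20) / 20, 0.15)
})

test_that("fits are scale- and time-unit-equivariant", {
  set.seed(21)
  t <- seq(30, 2400, length.out = 24)
  y <- (1200 - 2300 * exp(-t / 650)) + rnorm(24, 0, 12)
  s1 <- RelaxationSeries(t, y)
  f1 <- fitT1LookLocker(s1)
  # signal scaling k: a, b scale; T1*, T1 unchanged
  k <- 3.7
  f2 <- fitT1LookLocker(RelaxationSeries(t, k * y))
  expect_equal(f2@a / f1@a, k, tolerance = 1e-6)
  expect_equal(f2@b / f1@b, k, tolerance = 1e-6)
  expect_equal(f2@t1, f1@t1, tolerance = 1e-6)
  # time scaling k: T1*, T1 scale; a, b unchanged
  f3 <- fitT1LookLocker(RelaxationSeries(2 * t, y))
  expect_equal(f3@t1Star / f1@t1Star, 2, tolerance = 1e-6)
  expect_equal(f3@a, f1@a, tolerance = 1e-6)
  yd <- 1000 * exp(-defaultTESchedule() / 18) + 40 +
    rnorm(14, 0, 8)
  d1 <- fitT2MonoExp(RelaxationSeries(defaultTESchedule(), yd,
                                      kind = "echo_decay"))
  d2 <- fitT2MonoExp(RelaxationSeries(defaultTESchedule(), 5 * yd,
                                      kind = "echo_decay"))
  expect_equal(d2@t2, d1@t2, tolerance = 1e-6)
  expect_equal(d2@m0 / d1@m0, 5, tolerance = 1e-6)
  expect_equal(d2@c / d1@c, 5, tolerance = 1e-6)
})

test_that("exclusion flags and the auto-excluder drop corrupted points", {
  s <- irSignedSeries(1000, 1800, 600, n = 14)
  sig <- relaxSignals(s)
  sig[5] <- sig[5] * 10  # a motion-corrupted frame
  bad <- RelaxationSeries(relaxTimes(s), sig)
  excludedPoints(bad)[5] <- TRUE
  f <- fitT1LookLocker(bad)
  expect_equal(t1Value(f), 480, tolerance = 1e-6)
  expect_identical(f@nPointsUsed, 13L)
  # the optional automated flagger finds the same point
  fAuto <- fitT1LookLocker(RelaxationSeries(relaxTimes(s), sig),
                           autoExclude = TRUE)
  expect_equal(t1Value(fAuto), 480, tolerance = 1e-4)
})

test_that("roiMeanSeries averages ROI voxels and estimates noise sigma", {
  mk <- function(v) VolumeImage(array(v, c(4, 4, 4)), spacing = rep(1, 3))
  roi <- array(FALSE, c(4, 4, 4)); roi[1:2, 1, 1] <- TRUE
  s <- roiMeanSeries(list(mk(7), mk(7)), roi, times = c(10, 20))
  expect_equal(relaxSignals(s), c(7, 7))
  two <- mk(0); two@voxels[1, 1, 1] <- 10; two@voxels[2, 1, 1] <- 20
  expect_equal(relaxSignals(roiMeanSeries(list(two), roi, times = 10)), 15)
  # a background ROI over pure Rician noise recovers sigma via the
  # Rayleigh mean sigma * sqrt(pi / 2)
  set.seed(33)
  noise <- VolumeImage(array(sqrt(rnorm(8000, 0, 25)^2 +
                                  rnorm(8000, 0, 25)^2), c(20, 20, 20)),
                       spacing = rep(1, 3))
  bg <- roiMeanSeries(list(noise), array(TRUE, c(20, 20, 20)), times = 10,
                      roiName = "background")
  expect_lt(abs(backgroundSigma(bg) - 25) / 25, 0.05)
  expect_error(roiMeanSeries(list(mk(1)), array(FALSE, c(4, 4, 4)),
                             times = 10), "empty")
  expect_error(roiMeanSeries(list(mk(1)),
                             array(TRUE, c(3, 3, 3)), times = 10),
               "share one grid")
})

test_that("stability report computes percent deviations and CoV", {
  r <- stabilityReport(c(500, 500, 500))
  expect_equal(r@percentDeviation, rep(0, 3))
  expect_equal(r@cov, 0)
  r2 <- stabilityReport(c(98, 102))
  expect_equal(r2@percentDeviation, c(-2, 2))
  expect_equal(r2@cov, 100 * sd(c(98, 102)) / 100, tolerance = 1e-12)
  expect_error(stabilityReport(c(500)), "at least 2")
  expect_error(stabilityReport(c(-5, 3)), "mean")
  # deviations sum to ~0 when all timepoints are present
  r3 <- stabilityReport(c(480, 500, 512, 495))
  expect_equal(sum(r3@percentDeviation), 0, tolerance = 1e-10)
})
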