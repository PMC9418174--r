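# stain histomorphometry: features, pixel classifier, iron load

test_that("feature extraction is deterministic and respects scales", {
  flat <- array(0.5, c(8, 8, 3))
  f <- extractPixelFeatures(flat, scales = c(1, 2))
  expect_true(all(apply(f, 2, function(col) diff(range(col)) < 1e-9)))
  raw <- extractPixelFeatures(flat, scales = numeric(0),
                              useDeconvolution = FALSE)
  expect_identical(colnames(raw), c("R", "G", "B"))
  expect_error(extractPixelFeatures(flat, scales = c(0, 1)), "> 0")
  # smoothing spreads an isolated dark-blue pixel onto its neighbours
  img <- array(1, c(9, 9, 3))
  img[5, 5, 1:2] <- 0
  sm <- extractPixelFeatures(img, scales = 2, useDeconvolution = FALSE)
  rSm <- matrix(sm[, "R_s2"], 9, 9)
  expect_lt(rSm[5, 6], 1)
  expect_lt(rSm[5, 5], rSm[5, 6])
  expect_identical(sm, extractPixelFeatures(img, scales = 2,
                                            useDeconvolution = FALSE))
})

test_that("a separable two-colour training set is learned perfectly", {
  fx <- slideWithModel(frac = 0.3, size = 60, jitter = 0, seed = 2)
  expect_equal(fx$model@trainAccuracy, 1)
  pred <- predictPixels(fx$model, fx$slide$image)
  expect_identical(pred, fx$slide$truth)
})

test_that("training validates its annotations", {
  sl <- simulateStainImage(20, 20, 0.5, seed = 1)
  onlyNeg <- matrix(0L, 20, 20); onlyNeg[1:5] <- 1L
  expect_error(trainPixelModel(sl$image, onlyNeg), "positive and one negative")
  # identical colours, zero jitter: unlearnable
  flat <- StainImage(array(0.5, c(10, 10, 3)))
  ann <- matrix(0L, 10, 10); ann[1:3] <- 1L; ann[4:6] <- 2L
  expect_error(trainPixelModel(flat, ann), "unlearnable")
  wrongSize <- matrix(0L, 5, 5)
  expect_error(trainPixelModel(sl$image, wrongSize), "matching")
})

test_that("predictions are invariant to annotation supply order", {
  sl <- simulateStainImage(50, 50, 0.2, seed = 4)
  ann <- annotateFromTruth(sl$truth, n = 120, seed = 4)
  m1 <- trainPixelModel(sl$image, ann, seed = 9)
  # relabel the same pixel set through a transposed-scan annotation matrix
  ann2 <- matrix(0L, 50, 50)
  idx <- rev(which(ann > 0))
  ann2[idx] <- ann[idx]
  m2 <- trainPixelModel(sl$image, ann2, seed = 9)
  expect_identical(predictPixels(m1, sl$image),
                   predictPixels(m2, sl$image))
})

test_that("held-out pixel accuracy on a modest-jitter slide is >= 95%", {
  fx <- slideWithModel(frac = 0.18, size = 100, jitter = 0.04, seed = 5)
  pred <- predictPixels(fx$model, fx$slide$image)
  held <- fx$ann == 0L
  expect_gte(mean(pred[held] == fx$slide$truth[held]), 0.95)
})

test_that("iron load reports percent positive area over tissue pixels", {
  fx <- slideWithModel(frac = 0.18, size = 100, jitter = 0.03, seed = 6)
  res <- ironLoad(fx$slide$image, fx$model)
  expect_lt(abs(res$positivePct - 18), 1)
  expect_equal(res$positivePct, 100 * res$nPositive / res$nTissue)
  # all-negative slide -> 0 %
  neg <- simulateStainImage(40, 40, 0, jitterSD = 0.03, seed = 7)
  expect_equal(ironLoad(neg$image, fx$model)$positivePct, 0)
  # tissue mask restricted to a pure-positive region -> 100 %
  posMask <- fx$slide$truth
  expect_equal(ironLoad(fx$slide$image, fx$model,
                        tissue = posMask)$positivePct, 100)
  expect_error(ironLoad(fx$slide$image, fx$model,
                        tissue = matrix(FALSE, 100, 100)), "empty")
})

test_that("estimated fractions increase monotonically with the truth", {
  est <- vapply(c(0.05, 0.10, 0.20, 0.40), function(fr) {
    fx <- slideWithModel(frac = fr, size = 80, jitter = 0.04,
                         seed = round(1000 * fr))
    ironLoad(fx$slide$image, fx$model)$positivePct
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("the luminance tissue mask excludes bright background", {
  px <- array(1, c(10, 10, 3))        # white glass
  px[1:5, , ] <- 0.6                  # tissue
  expect_identical(unname(rowSums(tissueMask(px))),
                   c(rep(10, 5), rep(0, 5)))
})
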