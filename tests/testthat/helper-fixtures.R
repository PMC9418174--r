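# shared fixture builders; everything is generated in code

# noiseless signed IR series spanning ~3 T1* with n points
irSignedSeries <- function(a, b, t1Star, n = 12) {
  simulateIRSeries(seq(0.05 * t1Star, 3 * t1Star, length.out = n),
                   a = a, b = b, t1Star = t1Star, magnitude = FALSE)
}

decaySeries <- function(m0 = 1000, t2 = 14, c0 = 50, ...)
  simulateDecaySeries(defaultTESchedule(), m0 = m0, t2 = t2, c0 = c0, ...)

# cheap separable training slide plus sampled annotations
slideWithModel <- function(frac = 0.18, size = 100, jitter = 0.03,
                           seed = 1, nAnn = 150) {
  sl <- simulateStainImage(size, size, frac, jitterSD = jitter, seed = seed)
  ann <- annotateFromTruth(sl$truth, n = nAnn, seed = seed)
  list(slide = sl, ann = ann,
       model = trainPixelModel(sl$image, ann, seed = seed))
}
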