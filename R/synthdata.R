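# Synthetic-data generators: relaxation signal series, geometric label
# phantoms, two-color stained slides, and factorial longitudinal cohorts.
# Every generator is deterministic given its seed and reports its ground truth.

#' Default inversion-time schedule
#'
#' Uniform TI schedule starting at 7 ms. With the defaults (50 samples,
#' 80 ms increment) the schedule spans about 4 s, several times a typical
#' rodent-tissue T1, which is what a Look-Locker readout train samples.
#'
#' @param first first TI in ms.
#' @param by increment in ms.
#' @param n number of samples.
#' @return numeric vector of TIs in ms.
#' @export
defaultTISchedule <- function(first = 7, by = 80, n = 50)
  first + by * (seq_len(n) - 1)

#' Default echo-time schedule
#'
#' A 14-echo spin-echo train at 6 ms spacing (TE = 6..84 ms).
#'
#' @return numeric vector of TEs in ms.
#' @export
defaultTESchedule <- function() seq(6, 84, by = 6)

.checkSchedule <- function(schedule) {
  .assert(length(schedule) > 0, "schedule must not be empty")
  .assert(all(is.finite(schedule)) && all(schedule > 0),
          "all schedule times must be finite and > 0")
  .assert(.strictlyIncreasing(schedule),
          "schedule must be strictly increasing")
}

#' Simulate an inversion-recovery signal series
#'
#' Samples the Look-Locker recovery model
#' \eqn{S(TI) = a - b e^{-TI/T1^*}} on a TI schedule and perturbs it with
#' Rician noise (magnitude mode, the default for reconstructed MR
#' magnitude images) or additive Gaussian noise. Supplying `t1` instead of
#' `t1Star` converts through the Look-Locker relation
#' \eqn{T1 = T1^* (b/a - 1)}. Ideal inversion corresponds to `b = 2 a`.
#'
#' @param schedule TI sample times in ms, strictly increasing and positive.
#' @param a,b recovery model amplitudes (signal units), both > 0.
#' @param t1Star apparent T1 in ms (> 0). Give either `t1Star` or `t1`.
#' @param t1 corrected T1 in ms; converted to `t1Star = t1 / (b/a - 1)`
#'   (requires `b > a`).
#' @param noiseSigma noise scale in signal units (>= 0).
#' @param magnitude logical; if `TRUE` apply the magnitude operation
#'   (Rician noise; at `noiseSigma = 0` simply `|S|`), else signed signals
#'   with Gaussian noise.
#' @param seed integer seed; the caller's RNG state is untouched.
#' @param roiLabel ROI name stored in the series.
#' @return a [RelaxationSeries-class] of kind `"inversion_recovery"`.
#' @examples
#' s <- simulateIRSeries(c(100, 600, 3000), a = 1000, b = 1800,
#'                       t1Star = 600, magnitude = FALSE)
#' relaxSignals(s)[2]  # 1000 - 1800 * exp(-1)
#' @export
simulateIRSeries <- function(schedule = defaultTISchedule(), a = 1000,
                             b = 2000, t1Star = 600, t1 = NULL,
                             noiseSigma = 0, magnitude = TRUE, seed = NULL,
                             roiLabel = "marrow_L3") {
  .checkSchedule(schedule)
  .assert(is.finite(a) && a > 0, "'a' must be > 0")
  .assert(is.finite(b) && b > 0, "'b' must be > 0")
  .assert(is.finite(noiseSigma) && noiseSigma >= 0,
          "'noiseSigma' must be >= 0")
  if (!is.null(t1)) {
    .assert(is.finite(t1) && t1 > 0, "'t1' must be > 0")
    .assert(b > a, "converting t1 to t1Star requires b > a")
    t1Star <- t1 / (b / a - 1)
  }
  .assert(is.finite(t1Star) && t1Star > 0, "'t1Star' must be > 0")
  clean <- a - b * exp(-schedule / t1Star)
  signals <- .withSeed(seed, {
    if (noiseSigma == 0) {
      if (magnitude) abs(clean) else clean
    } else if (magnitude) {
      .riceNoise(clean, noiseSigma)
    } else {
      clean + stats::rnorm(length(clean), 0, noiseSigma)
    }
  })
  RelaxationSeries(schedule, signals, kind = "inversion_recovery",
                   roiLabel = roiLabel)
}

#' Simulate a multi-echo decay signal series
#'
#' Samples \eqn{S(TE) = M_0 e^{-TE/T2} + c} on a TE schedule with Rician
#' (magnitude mode) or Gaussian noise. An optional multiplicative bias on
#' the first echo emulates the stimulated-echo artifact that motivates
#' excluding echo 1 from T2 fitting; the bias is applied to the noiseless
#' signal before noise.
#'
#' @param schedule TE sample times in ms.
#' @param m0 initial signal intensity (> 0).
#' @param t2 transverse relaxation time in ms (> 0).
#' @param c0 noise-floor offset (>= 0).
#' @param noiseSigma,magnitude,seed,roiLabel as in [simulateIRSeries()].
#' @param firstEchoFactor multiplicative bias applied to echo 1 only
#'   (default 1 = no bias).
#' @return a [RelaxationSeries-class] of kind `"echo_decay"`.
#' @examples
#' s <- simulateDecaySeries(defaultTESchedule(), m0 = 1000, t2 = 14, c0 = 50)
#' @export
simulateDecaySeries <- function(schedule = defaultTESchedule(), m0 = 1000,
                                t2 = 20, c0 = 30, noiseSigma = 0,
                                magnitude = TRUE, seed = NULL,
                                firstEchoFactor = 1, roiLabel = "spleen") {
  .checkSchedule(schedule)
  .assert(is.finite(m0) && m0 > 0, "'m0' must be > 0")
  .assert(is.finite(t2) && t2 > 0, "'t2' must be > 0")
  .assert(is.finite(c0) && c0 >= 0, "'c0' must be >= 0")
  .assert(is.finite(noiseSigma) && noiseSigma >= 0,
          "'noiseSigma' must be >= 0")
  .assert(is.finite(firstEchoFactor) && firstEchoFactor > 0,
          "'firstEchoFactor' must be > 0")
  clean <- m0 * exp(-schedule / t2) + c0
  clean[1] <- clean[1] * firstEchoFactor
  signals <- .withSeed(seed, {
    if (noiseSigma == 0) {
      clean
    } else if (magnitude) {
      .riceNoise(clean, noiseSigma)
    } else {
      clean + stats::rnorm(length(clean), 0, noiseSigma)
    }
  })
  RelaxationSeries(schedule, signals, kind = "echo_decay",
                   roiLabel = roiLabel)
}

#' Describe one phantom shape
#'
#' @param label positive integer label id.
#' @param kind `"box"`, `"ellipsoid"` or `"tube"` (cylinder along z).
#' @param center shape centre in mm (length 3, world coordinates).
#' @param size for a box: full edge lengths (mm); for an ellipsoid: the
#'   three semi-axes (mm); for a tube: `c(radius, length)` in mm.
#' @return a shape descriptor list for [simulatePhantom()].
#' @export
phantomShape <- function(label, kind = c("box", "ellipsoid", "tube"),
                         center, size) {
  kind <- match.arg(kind)
  .assert(is.finite(label) && label > 0 && label == round(label),
          "shape label must be a positive integer")
  .assert(length(center) == 3L, "center must have length 3 (mm)")
  if (kind == "tube") .assert(length(size) == 2L,
                              "tube size must be c(radius, length)")
  else .assert(length(size) == 3L, "size must have length 3 (mm)")
  .assert(all(size > 0), "shape dimensions must be > 0")
  list(label = as.integer(label), kind = kind, center = as.numeric(center),
       size = as.numeric(size))
}

.analyticVolume <- function(shape) {
  switch(shape$kind,
         box       = prod(shape$size),
         ellipsoid = 4 / 3 * pi * prod(shape$size),
         tube      = pi * shape$size[1]^2 * shape$size[2])
}

#' Generate a geometric label phantom
#'
#' Builds an integer label mask on a voxel grid from analytic shapes, an
#' intensity image over the mask (with optional Rician noise), and the
#' analytic ground-truth volume of each shape. A voxel belongs to a shape
#' iff its centre does: box faces are half-open on the max side
#' (`lo <= x < hi`), quadric boundaries are included. Later shapes
#' overwrite earlier ones; duplicate label ids are an error.
#'
#' @param shapes list of [phantomShape()] descriptors (may be empty).
#' @param gridShape voxels per axis (length 3).
#' @param spacing mm per axis (length 3, > 0).
#' @param origin grid-corner offset in mm.
#' @param intensities named numeric vector, label id (as name) -> mean
#'   intensity; labels not listed default to `shapeIntensity`.
#' @param backgroundIntensity,shapeIntensity default mean intensities.
#' @param noiseSigma Rician noise scale on the image (0 = noiseless).
#' @param organs optional named integer vector (organ name -> label id)
#'   stored in the mask.
#' @param seed integer seed.
#' @return list with elements `image` ([VolumeImage-class]), `mask`
#'   ([LabelMask-class]) and `truth` (data.frame: label, kind,
#'   analytic volume mm^3, voxel count, voxel volume mm^3).
#' @examples
#' ph <- simulatePhantom(
#'   list(phantomShape(1, "box", c(1.1, 1.2, 1.25), c(2.2, 2.4, 2.5))),
#'   gridShape = c(20, 20, 20), spacing = c(0.22, 0.24, 0.25))
#' ph$truth
#' @export
simulatePhantom <- function(shapes = list(), gridShape = c(64, 64, 64),
                            spacing = c(0.22, 0.24, 0.25),
                            origin = c(0, 0, 0), intensities = NULL,
                            backgroundIntensity = 100, shapeIntensity = 400,
                            noiseSigma = 0, organs = integer(0),
                            seed = NULL) {
  .assert(length(gridShape) == 3L && all(gridShape >= 1),
          "gridShape must be 3 positive counts")
  .assert(length(spacing) == 3L && all(spacing > 0),
          "spacing must be 3 positive values (mm)")
  .assert(is.finite(noiseSigma) && noiseSigma >= 0,
          "'noiseSigma' must be >= 0")
  labs <- vapply(shapes, `[[`, integer(1), "label")
  if (anyDuplicated(labs))
    stop("duplicate shape labels: ", paste(unique(labs[duplicated(labs)]),
                                           collapse = ", "), call. = FALSE)
  gridShape <- as.integer(gridShape)
  extent <- origin + gridShape * spacing

  # world coordinates of voxel centres, one vector per axis
  ax <- lapply(1:3, function(d)
    origin[d] + (seq_len(gridShape[d]) - 0.5) * spacing[d])
  mask <- array(0L, dim = gridShape)
  cx <- array(rep(ax[[1]], times = prod(gridShape[2:3])), dim = gridShape)
  cy <- array(rep(rep(ax[[2]], each = gridShape[1]), times = gridShape[3]),
              dim = gridShape)
  cz <- array(rep(ax[[3]], each = prod(gridShape[1:2])), dim = gridShape)

  truth <- data.frame(label = integer(0), kind = character(0),
                      analyticVolumeMm3 = numeric(0), nVoxels = integer(0),
                      voxelVolumeMm3 = numeric(0))
  for (sh in shapes) {
    inside <- switch(sh$kind,
      box = {
        lo <- sh$center - sh$size / 2; hi <- sh$center + sh$size / 2
        .assert(all(lo >= origin - 1e-9) && all(hi <= extent + 1e-9),
                sprintf("shape %d extends outside the grid", sh$label))
        (cx >= lo[1] & cx < hi[1]) & (cy >= lo[2] & cy < hi[2]) &
          (cz >= lo[3] & cz < hi[3])
      },
      ellipsoid = {
        .assert(all(sh$center - sh$size >= origin - 1e-9) &&
                all(sh$center + sh$size <= extent + 1e-9),
                sprintf("shape %d extends outside the grid", sh$label))
        ((cx - sh$center[1]) / sh$size[1])^2 +
          ((cy - sh$center[2]) / sh$size[2])^2 +
          ((cz - sh$center[3]) / sh$size[3])^2 <= 1
      },
      tube = {
        r <- sh$size[1]; len <- sh$size[2]
        zlo <- sh$center[3] - len / 2; zhi <- sh$center[3] + len / 2
        .assert(all(sh$center[1:2] - r >= origin[1:2] - 1e-9) &&
                all(sh$center[1:2] + r <= extent[1:2] + 1e-9) &&
                zlo >= origin[3] - 1e-9 && zhi <= extent[3] + 1e-9,
                sprintf("shape %d extends outside the grid", sh$label))
        ((cx - sh$center[1])^2 + (cy - sh$center[2])^2 <= r^2) &
          (cz >= zlo & cz < zhi)
      })
    mask[inside] <- sh$label
  }
  voxVol <- prod(spacing)
  for (sh in shapes)
    truth <- rbind(truth, data.frame(
      label = sh$label, kind = sh$kind,
      analyticVolumeMm3 = .analyticVolume(sh),
      nVoxels = sum(mask == sh$label), voxelVolumeMm3 = voxVol))

  clean <- array(backgroundIntensity, dim = gridShape)
  for (sh in shapes) {
    mu <- if (!is.null(intensities) &&
              as.character(sh$label) %in% names(intensities))
      intensities[[as.character(sh$label)]] else shapeIntensity
    clean[mask == sh$label] <- mu
  }
  vox <- .withSeed(seed, {
    if (noiseSigma == 0) clean
    else array(.riceNoise(as.vector(clean), noiseSigma), dim = gridShape)
  })
  list(image = VolumeImage(vox, spacing, origin),
       mask = LabelMask(mask, spacing, organs = organs, origin = origin),
       truth = truth)
}

#' Generate a synthetic two-color stained slide
#'
#' Draws exactly `round(positiveFraction * width * height)` pixels as
#' stain-positive (spatially at random), colours the two classes around
#' their class colours with per-channel Gaussian jitter, and returns the
#' ground-truth positive mask. Default colours approximate a Prussian-blue
#' positive class on a nuclear-red counterstained background.
#'
#' @param width,height image size in pixels.
#' @param positiveFraction true positive-area fraction in \[0, 1\].
#' @param positiveColor,negativeColor RGB class colours in \[0, 1\].
#' @param jitterSD per-channel Gaussian colour jitter sd (values are
#'   clamped back to \[0, 1\]).
#' @param seed integer seed.
#' @param slideId slide identifier.
#' @return list with `image` ([StainImage-class]) and `truth` (logical
#'   height x width matrix, `TRUE` = positive).
#' @examples
#' sl <- simulateStainImage(64, 64, 0.18, seed = 1)
#' mean(sl$truth)
#' @export
simulateStainImage <- function(width = 256, height = 256,
                               positiveFraction = 0.15,
                               positiveColor = c(0.20, 0.30, 0.62),
                               negativeColor = c(0.88, 0.62, 0.66),
                               jitterSD = 0.03, seed = NULL,
                               slideId = "synthetic") {
  .assert(positiveFraction >= 0 && positiveFraction <= 1,
          "'positiveFraction' must lie in [0, 1]")
  .assert(length(positiveColor) == 3L && length(negativeColor) == 3L &&
          all(c(positiveColor, negativeColor) >= 0) &&
          all(c(positiveColor, negativeColor) <= 1),
          "class colours must be RGB triples in [0, 1]")
  .assert(jitterSD >= 0, "'jitterSD' must be >= 0")
  n <- as.integer(width) * as.integer(height)
  nPos <- round(positiveFraction * n)
  if (nPos > 0 && nPos < n && jitterSD == 0 &&
      all(positiveColor == negativeColor))
    stop("degenerate configuration: identical class colours with zero ",
         "jitter and both classes present is unlearnable", call. = FALSE)
  .withSeed(seed, {
    truth <- matrix(FALSE, nrow = height, ncol = width)
    if (nPos > 0) truth[sample.int(n, nPos)] <- TRUE
    px <- array(0, dim = c(height, width, 3))
    for (ch in 1:3) {
      base <- ifelse(truth, positiveColor[ch], negativeColor[ch])
      if (jitterSD > 0) base <- base + stats::rnorm(n, 0, jitterSD)
      px[, , ch] <- pmin(1, pmax(0, base))
    }
    list(image = StainImage(px, slideId = slideId), truth = truth)
  })
}

#' Default cohort effect configuration
#'
#' Measurement generators for a 2 sex x 2 genotype longitudinal cohort:
#' per-timepoint baseline curve, additive genotype effect (applied to
#' mutants; scalar or per-timepoint), additive sex effect (applied to
#' males) and Gaussian residual sd. The defaults emulate the measurement
#' panel of a KIT-mutant GIST-model monitoring study: body weight (g),
#' spleen and cecum volume (mm^3), vertebral marrow T1 and splenic T2
#' (ms), and Peyer's-patch counts — with a late-age marrow T1 shortening
#' in mutants, a sex difference in splenic T2 (females shorter, i.e.
#' higher iron), an early cecal volume decrease turning into a late
#' increase, and several-fold more Peyer's patches in mutants.
#'
#' @param timepoints schedule in months.
#' @return named list of effect descriptors for [simulateCohort()].
#' @export
defaultCohortEffects <- function(timepoints = c(2, 4, 6, 8, 10, 12)) {
  tp <- timepoints
  interp <- function(vals) stats::approx(c(2, 4, 6, 8, 10, 12), vals, tp,
                                         rule = 2)$y
  list(
    body_weight = list(baseline = interp(c(22, 26, 28, 30, 31, 31)),
                       genotype = interp(c(0, 0, -0.5, -1.5, -2, -2.5)),
                       sex = 5, sd = 1.8),
    spleen_volume = list(baseline = interp(c(85, 95, 100, 105, 105, 110)),
                         genotype = 0, sex = -15, sd = 10),
    cecum_volume = list(baseline = interp(c(300, 320, 340, 350, 360, 370)),
                        genotype = interp(c(-40, -30, 0, 20, 40, 60)),
                        sex = 10, sd = 30),
    marrow_T1 = list(baseline = interp(c(520, 515, 510, 505, 500, 495)),
                     genotype = interp(c(0, 0, -5, -10, -20, -40)),
                     sex = 0, sd = 15),
    spleen_T2 = list(baseline = rep(16, length(tp)),
                     genotype = 0, sex = 2, sd = 0.8),
    muscle_T2 = list(baseline = rep(26, length(tp)),
                     genotype = 0, sex = 0, sd = 0.5),
    peyers_patches = list(baseline = rep(4, length(tp)),
                          genotype = 14, sex = 0, sd = 1.5))
}

#' Default tumor-onset model
#'
#' Per-timepoint onset hazards by genotype and sex, an initial tumor
#' volume and a per-interval geometric growth factor. Defaults reflect a
#' mammary/splenic tumor pattern concentrated in mutant females with onset
#' from mid-study, sub-mm^3 first detection and strong per-interval growth.
#'
#' @param timepoints schedule in months.
#' @return list with `hazard` (named list `genotype_sex` -> per-timepoint
#'   hazard), `initialVolume` (mm^3) and `growthFactor` (> 0).
#' @export
defaultTumorModel <- function(timepoints = c(2, 4, 6, 8, 10, 12)) {
  k <- length(timepoints)
  ramp <- function(p) { h <- numeric(k); h[timepoints >= 6] <- p; h }
  list(hazard = list(mutant_f = ramp(0.20), mutant_m = ramp(0.04),
                     control_f = numeric(k), control_m = numeric(k)),
       initialVolume = 0.5, growthFactor = 4)
}

.checkEffects <- function(effects, nT) {
  .assert(is.list(effects) && length(effects) > 0 &&
          !is.null(names(effects)) && all(nzchar(names(effects))),
          "'effects' must be a named list of measurement descriptors")
  for (m in names(effects)) {
    e <- effects[[m]]
    miss <- setdiff(c("baseline", "genotype", "sex", "sd"), names(e))
    if (length(miss))
      stop(sprintf("effects['%s'] is missing field(s): %s", m,
                   paste(miss, collapse = ", ")), call. = FALSE)
    for (f in c("baseline", "genotype", "sex"))
      if (!length(e[[f]]) %in% c(1L, nT))
        stop(sprintf("effects['%s']$%s must be scalar or one per timepoint",
                     m, f), call. = FALSE)
    if (!(is.numeric(e$sd) && length(e$sd) == 1L && e$sd >= 0))
      stop(sprintf("effects['%s']$sd must be a single value >= 0", m),
           call. = FALSE)
  }
}

#' Simulate a factorial longitudinal cohort
#'
#' Generates a 2 sex x 2 genotype cohort of `nPerGroup` animals per cell
#' measured at each timepoint. Each measurement value is
#' `baseline(timepoint) + genotype_effect * is_mutant + sex_effect *
#' is_male + N(0, sd)`. Tumors arise per animal from a per-timepoint onset
#' hazard (by genotype and sex) and, once present, grow geometrically per
#' interval; they appear as measurement `"tumor_volume"` from the onset
#' timepoint onward. Deterministic given the seed.
#'
#' @param nPerGroup animals per sex x genotype cell (>= 2).
#' @param timepoints increasing ages in months.
#' @param effects named list of measurement descriptors, see
#'   [defaultCohortEffects()]; the `measurements` argument must name a
#'   subset of it.
#' @param tumorModel see [defaultTumorModel()]; `NULL` disables tumors.
#' @param measurements which measurements to generate.
#' @param seed integer seed.
#' @return a [CohortTable-class].
#' @examples
#' coh <- simulateCohort(nPerGroup = 3, seed = 1)
#' head(cohortData(coh))
#' @export
simulateCohort <- function(nPerGroup = 7, timepoints = c(2, 4, 6, 8, 10, 12),
                           effects = defaultCohortEffects(timepoints),
                           tumorModel = defaultTumorModel(timepoints),
                           measurements = names(effects), seed = NULL) {
  .assert(nPerGroup >= 2, "'nPerGroup' must be >= 2")
  .assert(length(timepoints) >= 1 && .strictlyIncreasing(timepoints),
          "'timepoints' must be increasing")
  nT <- length(timepoints)
  .checkEffects(effects, nT)
  unknown <- setdiff(measurements, names(effects))
  if (length(unknown))
    stop("unknown measurement name(s) in effects: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(tumorModel)) {
    .assert(all(c("hazard", "initialVolume", "growthFactor") %in%
                names(tumorModel)), "malformed 'tumorModel'")
    .assert(tumorModel$growthFactor > 0, "tumor growth factor must be > 0")
    .assert(tumorModel$initialVolume > 0, "initial tumor volume must be > 0")
  }
  grid <- expand.grid(sex = c("f", "m"), genotype = c("mutant", "control"),
                      idx = seq_len(nPerGroup), stringsAsFactors = FALSE)
  grid <- grid[order(grid$genotype, grid$sex, grid$idx), ]
  grid$animal <- sprintf("%s_%s_%02d", substr(grid$genotype, 1, 3),
                         grid$sex, grid$idx)
  expandEff <- function(x) if (length(x) == 1L) rep(x, nT) else x

  .withSeed(seed, {
    rows <- vector("list", nrow(grid) * (length(measurements) + 1L))
    k <- 0L
    for (i in seq_len(nrow(grid))) {
      an <- grid[i, ]
      isMut <- an$genotype == "mutant"
      isMale <- an$sex == "m"
      for (m in measurements) {
        e <- effects[[m]]
        mu <- expandEff(e$baseline) + expandEff(e$genotype) * isMut +
          expandEff(e$sex) * isMale
        val <- mu + if (e$sd > 0) stats::rnorm(nT, 0, e$sd) else 0
        k <- k + 1L
        rows[[k]] <- data.frame(animal = an$animal, sex = an$sex,
                                genotype = an$genotype,
                                timepoint = timepoints, measurement = m,
                                value = val, excluded = FALSE, reason = "")
      }
      if (!is.null(tumorModel)) {
        h <- tumorModel$hazard[[paste(an$genotype, an$sex, sep = "_")]]
        if (is.null(h)) h <- numeric(nT)
        u <- stats::runif(nT)
        onset <- which(u < h)[1]
        if (!is.na(onset)) {
          idx <- onset:nT
          vol <- tumorModel$initialVolume *
            tumorModel$growthFactor^(seq_along(idx) - 1)
          k <- k + 1L
          rows[[k]] <- data.frame(animal = an$animal, sex = an$sex,
                                  genotype = an$genotype,
                                  timepoint = timepoints[idx],
                                  measurement = "tumor_volume", value = vol,
                                  excluded = FALSE, reason = "")
        }
      }
    }
    CohortTable(do.call(rbind, rows[seq_len(k)]), timepoints = timepoints)
  })
}
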