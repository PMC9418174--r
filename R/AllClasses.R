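#' @import methods
NULL

#' RelaxationSeries: sampled ROI signal versus inversion or echo time
#'
#' Container for one region of interest's mean signal sampled along an
#' inversion-time (TI) or echo-time (TE) schedule, with per-point exclusion
#' flags (used e.g. to drop motion-corrupted frames) and an optional
#' background-noise scale estimated from a noise ROI.
#'
#' @slot kind either `"inversion_recovery"` (TI series) or `"echo_decay"`
#'   (TE series).
#' @slot times sample times in ms, strictly increasing.
#' @slot signals signal intensities (arbitrary units), same length as times.
#' @slot excluded logical exclusion flags, same length as times.
#' @slot roiLabel free-text ROI name (e.g. `"marrow_L3"`).
#' @slot backgroundSigma Rician noise scale in signal units, or `NA`.
#'
#' @seealso [RelaxationSeries()], [fitT1LookLocker()], [fitT2MonoExp()]
#' @exportClass RelaxationSeries
setClass("RelaxationSeries",
  representation(kind = "character", times = "numeric", signals = "numeric",
                 excluded = "logical", roiLabel = "character",
                 backgroundSigma = "numeric"),
  prototype(kind = "inversion_recovery", times = numeric(0),
            signals = numeric(0), excluded = logical(0), roiLabel = "",
            backgroundSigma = NA_real_),
  validity = function(object) {
    msg <- character(0)
    if (!object@kind %in% c("inversion_recovery", "echo_decay"))
      msg <- c(msg, "kind must be 'inversion_recovery' or 'echo_decay'")
    if (length(object@signals) != length(object@times))
      msg <- c(msg, "times and signals must have equal length")
    if (length(object@excluded) != length(object@times))
      msg <- c(msg, "excluded flags must match times in length")
    if (anyNA(object@times) || any(object@times <= 0))
      msg <- c(msg, "all sample times must be finite and > 0")
    if (!.strictlyIncreasing(object@times))
      msg <- c(msg, "sample times must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' Construct a RelaxationSeries
#'
#' @param times sample times (TI or TE) in ms, strictly increasing, > 0.
#' @param signals signal intensities, same length as `times`.
#' @param kind `"inversion_recovery"` or `"echo_decay"`.
#' @param excluded logical exclusion flags (default none excluded).
#' @param roiLabel ROI name.
#' @param backgroundSigma optional Rician noise scale (signal units).
#' @return a [RelaxationSeries-class] object.
#' @examples
#' s <- RelaxationSeries(c(50, 500, 2000), c(-800, 100, 950))
#' relaxTimes(s)
#' @export
RelaxationSeries <- function(times, signals,
                             kind = c("inversion_recovery", "echo_decay"),
                             excluded = rep(FALSE, length(times)),
                             roiLabel = "", backgroundSigma = NA_real_) {
  kind <- match.arg(kind)
  new("RelaxationSeries", kind = kind, times = as.numeric(times),
      signals = as.numeric(signals), excluded = as.logical(excluded),
      roiLabel = as.character(roiLabel),
      backgroundSigma = as.numeric(backgroundSigma))
}

#' T1 fit result (Look-Locker inversion recovery)
#'
#' Parameters of the three-parameter recovery model
#' \eqn{S(TI) = a - b e^{-TI/T1^*}} together with the corrected
#' \eqn{T1 = T1^* (b/a - 1)} and fit diagnostics.
#'
#' @slot a,b,t1Star fitted model parameters (signal units, signal units, ms).
#' @slot t1 corrected longitudinal relaxation time in ms.
#' @slot residualRMS root-mean-square residual over the points used.
#' @slot nPointsUsed number of non-excluded points entering the fit.
#' @slot converged logical; `FALSE` flags solver failure or a degenerate
#'   solution (\eqn{b/a \le 1}, i.e. non-positive T1).
#' @slot polarityFlipIndex number of leading points whose sign was restored
#'   before fitting magnitude data (0 for signed input).
#' @slot iterations IRLS iterations run.
#' @slot message diagnostic text for non-converged fits.
#' @exportClass T1Fit
setClass("T1Fit",
  representation(a = "numeric", b = "numeric", t1Star = "numeric",
                 t1 = "numeric", residualRMS = "numeric",
                 nPointsUsed = "integer", converged = "logical",
                 polarityFlipIndex = "integer", iterations = "integer",
                 message = "character"))

#' T2 fit result (mono-exponential decay with offset)
#'
#' Parameters of \eqn{S(TE) = M_0 e^{-TE/T2} + c}, where the offset `c`
#' accounts for the Rician noise floor of magnitude images, plus diagnostics.
#'
#' @slot m0 initial signal intensity (signal units).
#' @slot t2 transverse relaxation time in ms.
#' @slot c noise-floor offset (signal units).
#' @slot residualRMS root-mean-square residual over the points used.
#' @slot nPointsUsed number of points used (echo 1 is always excluded).
#' @slot converged logical convergence/validity flag.
#' @slot iterations IRLS iterations run.
#' @slot message diagnostic text for non-converged fits.
#' @exportClass T2Fit
setClass("T2Fit",
  representation(m0 = "numeric", t2 = "numeric", c = "numeric",
                 residualRMS = "numeric", nPointsUsed = "integer",
                 converged = "logical", iterations = "integer",
                 message = "character"))

#' VolumeImage: 3D scalar voxel grid with physical spacing
#'
#' @slot voxels 3D numeric array.
#' @slot spacing voxel edge lengths in mm per axis (length 3, > 0).
#' @slot origin world-coordinate offset in mm of the grid corner (length 3).
#'   The centre of voxel (i, j, k) (1-based) sits at
#'   `origin + (index - 0.5) * spacing`.
#' @exportClass VolumeImage
setClass("VolumeImage",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(dim(object@voxels)) != 3L)
      msg <- c(msg, "voxels must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive values (mm)")
    if (length(object@origin) != 3L)
      msg <- c(msg, "origin must have length 3")
    if (length(msg)) msg else TRUE
  })

#' Construct a VolumeImage
#' @param voxels 3D numeric array.
#' @param spacing mm per axis (length 3).
#' @param origin grid-corner offset in mm (default `c(0, 0, 0)`).
#' @return a [VolumeImage-class].
#' @export
VolumeImage <- function(voxels, spacing, origin = c(0, 0, 0)) {
  new("VolumeImage", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' LabelMask: integer organ labels on a voxel grid
#'
#' @slot labels 3D integer array; 0 is background.
#' @slot spacing,origin grid geometry as for [VolumeImage-class].
#' @slot organs named integer vector mapping organ name to label id,
#'   e.g. `c(spleen = 1L, cecum = 2L, tumor = 3L)`.
#' @exportClass LabelMask
setClass("LabelMask",
  representation(labels = "array", spacing = "numeric", origin = "numeric",
                 organs = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (length(dim(object@labels)) != 3L)
      msg <- c(msg, "labels must be a 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive values (mm)")
    if (length(object@organs) &&
        (is.null(names(object@organs)) || any(!nzchar(names(object@organs)))))
      msg <- c(msg, "organs must be a named integer vector (name -> label id)")
    if (anyDuplicated(object@organs))
      msg <- c(msg, "organ label ids must be unique")
    if (any(object@organs <= 0))
      msg <- c(msg, "organ label ids must be positive")
    if (length(msg)) msg else TRUE
  })

#' Construct a LabelMask
#' @param labels 3D integer array (0 = background).
#' @param spacing mm per axis.
#' @param organs named integer vector, organ name -> label id.
#' @param origin grid-corner offset in mm.
#' @return a [LabelMask-class].
#' @export
LabelMask <- function(labels, spacing, organs = integer(0),
                      origin = c(0, 0, 0)) {
  storage.mode(labels) <- "integer"
  new("LabelMask", labels = labels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), organs = as.integer2(organs))
}

# keep names when coercing to integer
as.integer2 <- function(x) { y <- as.integer(x); names(y) <- names(x); y }

#' StainImage: RGB histology image with physical pixel size
#'
#' @slot pixels height x width x 3 array, channel values in \[0, 1\].
#' @slot pixelSize pixel edge length in micrometres, or `NA`.
#' @slot slideId slide identifier.
#' @exportClass StainImage
setClass("StainImage",
  representation(pixels = "array", pixelSize = "numeric",
                 slideId = "character"),
  validity = function(object) {
    msg <- character(0)
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3] != 3L)
      msg <- c(msg, "pixels must be a height x width x 3 array")
    if (any(object@pixels < 0 | object@pixels > 1, na.rm = TRUE))
      msg <- c(msg, "channel values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Construct a StainImage
#' @param pixels height x width x 3 array in \[0, 1\].
#' @param pixelSize micrometres per pixel (optional).
#' @param slideId slide identifier.
#' @return a [StainImage-class].
#' @export
StainImage <- function(pixels, pixelSize = NA_real_, slideId = "") {
  new("StainImage", pixels = pixels, pixelSize = as.numeric(pixelSize),
      slideId = as.character(slideId))
}

#' PixelModel: trained per-pixel stain classifier
#'
#' @slot classifier the fitted model object (ranger forest or MASS lda).
#' @slot method `"forest"` or `"lda"`.
#' @slot featureSpec list describing the feature extraction (smoothing
#'   scales, stain-separation settings); predictions re-use it verbatim.
#' @slot classes class labels, always `c("negative", "positive")`.
#' @slot trainAccuracy training-set accuracy on the labelled pixels.
#' @slot meta list: slide id, number of labelled pixels, seed.
#' @exportClass PixelModel
setClass("PixelModel",
  representation(classifier = "ANY", method = "character",
                 featureSpec = "list", classes = "character",
                 trainAccuracy = "numeric", meta = "list"))

#' CohortTable: long-format longitudinal cohort records
#'
#' One row per animal x timepoint x measurement, in a 2 sex x 2 genotype
#' factorial design, with exclusion flags and reasons carried alongside.
#'
#' @slot records data.frame with columns `animal`, `sex` (`"f"`/`"m"`),
#'   `genotype` (`"mutant"`/`"control"`), `timepoint` (months),
#'   `measurement`, `value`, `excluded`, `reason`.
#' @slot timepoints the declared measurement schedule in months.
#' @exportClass CohortTable
setClass("CohortTable",
  representation(records = "data.frame", timepoints = "numeric"),
  validity = function(object) {
    msg <- character(0)
    need <- c("animal", "sex", "genotype", "timepoint", "measurement",
              "value", "excluded", "reason")
    miss <- setdiff(need, names(object@records))
    if (length(miss))
      msg <- c(msg, paste("records missing columns:",
                          paste(miss, collapse = ", ")))
    if (!length(msg)) {
      r <- object@records
      if (!all(r$sex %in% c("f", "m")))
        msg <- c(msg, "sex must be 'f' or 'm'")
      if (!all(r$genotype %in% c("mutant", "control")))
        msg <- c(msg, "genotype must be 'mutant' or 'control'")
      if (!all(r$timepoint %in% object@timepoints))
        msg <- c(msg, "timepoints must come from the declared schedule")
      key <- paste(r$animal, r$timepoint, r$measurement, sep = "\r")
      if (anyDuplicated(key))
        msg <- c(msg, "one value per animal x timepoint x measurement required")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a CohortTable
#' @param records long-format data.frame (see [CohortTable-class]).
#' @param timepoints declared schedule in months (defaults to the sorted
#'   unique timepoints present).
#' @return a [CohortTable-class].
#' @export
CohortTable <- function(records, timepoints = sort(unique(records$timepoint))) {
  if (!"excluded" %in% names(records)) records$excluded <- FALSE
  if (!"reason" %in% names(records)) records$reason <- ""
  new("CohortTable", records = as.data.frame(records),
      timepoints = as.numeric(timepoints))
}

#' StabilityReport: longitudinal internal-reference stability of one tissue
#'
#' Per-timepoint percent deviation from an animal's mean value and the
#' coefficient of variation, used to check serial measurement stability
#' against an internal reference tissue.
#'
#' @slot animal,tissue identifiers.
#' @slot timepoints,values the longitudinal measurements.
#' @slot meanValue per-animal mean over timepoints.
#' @slot percentDeviation per-timepoint `100 * (value - mean) / mean`.
#' @slot cov coefficient of variation, `100 * sd / mean` (percent).
#' @exportClass StabilityReport
setClass("StabilityReport",
  representation(animal = "character", tissue = "character",
                 timepoints = "numeric", values = "numeric",
                 meanValue = "numeric", percentDeviation = "numeric",
                 cov = "numeric"))

#' RunManifest: provenance record of one pipeline run
#'
#' @slot configHash md5 of the canonicalised run configuration.
#' @slot version package version string.
#' @slot outputDir output directory.
#' @slot stages named list; per completed stage, the files written (with
#'   md5 checksums) and record counts.
#' @slot warnings character vector (exclusions, truncated masks,
#'   non-converged fits).
#' @exportClass RunManifest
setClass("RunManifest",
  representation(configHash = "character", version = "character",
                 outputDir = "character", stages = "list",
                 warnings = "character"))
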