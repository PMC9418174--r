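# Accessor generics and show methods.

#' @name accessors
#' @title Accessors for MRImetry data classes
#' @description Slot accessors for the package's S4 containers; user code
#'   should use these rather than `@`.
#' @param x an MRImetry S4 object.
#' @param value replacement value.
#' @return the slot content (or, for replacement forms, the updated object).
NULL

#' @rdname accessors
#' @export
setGeneric("relaxKind", function(x) standardGeneric("relaxKind"))
#' @rdname accessors
#' @export
setGeneric("relaxTimes", function(x) standardGeneric("relaxTimes"))
#' @rdname accessors
#' @export
setGeneric("relaxSignals", function(x) standardGeneric("relaxSignals"))
#' @rdname accessors
#' @export
setGeneric("excludedPoints", function(x) standardGeneric("excludedPoints"))
#' @rdname accessors
#' @export
setGeneric("excludedPoints<-",
           function(x, value) standardGeneric("excludedPoints<-"))
#' @rdname accessors
#' @export
setGeneric("roiLabel", function(x) standardGeneric("roiLabel"))
#' @rdname accessors
#' @export
setGeneric("backgroundSigma", function(x) standardGeneric("backgroundSigma"))

#' @rdname accessors
#' @export
setMethod("relaxKind", "RelaxationSeries", function(x) x@kind)
#' @rdname accessors
#' @export
setMethod("relaxTimes", "RelaxationSeries", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("relaxSignals", "RelaxationSeries", function(x) x@signals)
#' @rdname accessors
#' @export
setMethod("excludedPoints", "RelaxationSeries", function(x) x@excluded)
#' @rdname accessors
#' @export
setReplaceMethod("excludedPoints", "RelaxationSeries", function(x, value) {
  x@excluded <- as.logical(value)
  validObject(x)
  x
})
#' @rdname accessors
#' @export
setMethod("roiLabel", "RelaxationSeries", function(x) x@roiLabel)
#' @rdname accessors
#' @export
setMethod("backgroundSigma", "RelaxationSeries", function(x) x@backgroundSigma)

#' @rdname accessors
#' @export
setGeneric("t1Value", function(x) standardGeneric("t1Value"))
#' @rdname accessors
#' @export
setGeneric("t2Value", function(x) standardGeneric("t2Value"))
#' @rdname accessors
#' @export
setGeneric("fitParams", function(x) standardGeneric("fitParams"))
#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setMethod("t1Value", "T1Fit", function(x) x@t1)
#' @rdname accessors
#' @export
setMethod("t2Value", "T2Fit", function(x) x@t2)
#' @rdname accessors
#' @export
setMethod("fitParams", "T1Fit",
          function(x) c(a = x@a, b = x@b, t1Star = x@t1Star, t1 = x@t1))
#' @rdname accessors
#' @export
setMethod("fitParams", "T2Fit",
          function(x) c(m0 = x@m0, t2 = x@t2, c = x@c))
#' @rdname accessors
#' @export
setMethod("isConverged", "T1Fit", function(x) x@converged)
#' @rdname accessors
#' @export
setMethod("isConverged", "T2Fit", function(x) x@converged)

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))
#' @rdname accessors
#' @export
setGeneric("organLabels", function(x) standardGeneric("organLabels"))

#' @rdname accessors
#' @export
setMethod("voxelData", "VolumeImage", function(x) x@voxels)
#' @rdname accessors
#' @export
setMethod("voxelData", "LabelMask", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "VolumeImage", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "LabelMask", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelOrigin", "VolumeImage", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("voxelOrigin", "LabelMask", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("organLabels", "LabelMask", function(x) x@organs)

#' @rdname accessors
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))
#' @rdname accessors
#' @export
setGeneric("slideId", function(x) standardGeneric("slideId"))
#' @rdname accessors
#' @export
setMethod("pixelData", "StainImage", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("slideId", "StainImage", function(x) x@slideId)

#' @rdname accessors
#' @export
setGeneric("cohortData", function(x) standardGeneric("cohortData"))
#' @rdname accessors
#' @export
setGeneric("cohortTimepoints", function(x) standardGeneric("cohortTimepoints"))
#' @rdname accessors
#' @export
setMethod("cohortData", "CohortTable", function(x) x@records)
#' @rdname accessors
#' @export
setMethod("cohortTimepoints", "CohortTable", function(x) x@timepoints)

setMethod("show", "RelaxationSeries", function(object) {
  cat(sprintf("RelaxationSeries (%s) '%s': %d points, %d excluded\n",
              object@kind, object@roiLabel, length(object@times),
              sum(object@excluded)))
  cat(sprintf("  times %s..%s ms; signal range [%.4g, %.4g]\n",
              format(min(object@times)), format(max(object@times)),
              min(object@signals), max(object@signals)))
  if (!is.na(object@backgroundSigma))
    cat(sprintf("  background sigma: %.4g\n", object@backgroundSigma))
})

setMethod("show", "T1Fit", function(object) {
  cat(sprintf(
    "T1Fit: T1 = %.2f ms (T1* = %.2f, a = %.4g, b = %.4g)\n",
    object@t1, object@t1Star, object@a, object@b))
  cat(sprintf("  %d points, rms %.4g, flip index %d, converged: %s\n",
              object@nPointsUsed, object@residualRMS,
              object@polarityFlipIndex, object@converged))
  if (nzchar(object@message)) cat("  note:", object@message, "\n")
})

setMethod("show", "T2Fit", function(object) {
  cat(sprintf("T2Fit: T2 = %.3f ms (M0 = %.4g, c = %.4g)\n",
              object@t2, object@m0, object@c))
  cat(sprintf("  %d points (echo 1 excluded), rms %.4g, converged: %s\n",
              object@nPointsUsed, object@residualRMS, object@converged))
  if (nzchar(object@message)) cat("  note:", object@message, "\n")
})

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("VolumeImage %dx%dx%d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing), collapse = " x ")))
})

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabelMask %dx%dx%d voxels, spacing %s mm\n", d[1], d[2], d[3],
              paste(format(object@spacing), collapse = " x ")))
  if (length(object@organs))
    cat("  organs:", paste(sprintf("%s=%d", names(object@organs),
                                   object@organs), collapse = ", "), "\n")
})

setMethod("show", "StainImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("StainImage '%s': %d x %d px", object@slideId, d[1], d[2]))
  if (!is.na(object@pixelSize))
    cat(sprintf(" (%.3g um/px)", object@pixelSize))
  cat("\n")
})

setMethod("show", "PixelModel", function(object) {
  cat(sprintf("PixelModel (%s): trained on %d labelled pixels, accuracy %.3f\n",
              object@method, object@meta$nLabeled, object@trainAccuracy))
})

setMethod("show", "CohortTable", function(object) {
  r <- object@records
  cat(sprintf(
    "CohortTable: %d records, %d animals, %d timepoints, %d measurements\n",
    nrow(r), length(unique(r$animal)), length(object@timepoints),
    length(unique(r$measurement))))
  cat(sprintf("  %d records excluded\n", sum(r$excluded)))
})

setMethod("show", "StabilityReport", function(object) {
  cat(sprintf("StabilityReport %s / %s over %d timepoints\n", object@animal,
              object@tissue, length(object@timepoints)))
  cat(sprintf("  mean %.4g; deviations %s%%; CoV %.3f%%\n", object@meanValue,
              paste(sprintf("%+.2f", object@percentDeviation),
                    collapse = ", "), object@cov))
})

setMethod("show", "RunManifest", function(object) {
  cat(sprintf("RunManifest (v%s, config %s)\n", object@version,
              substr(object@configHash, 1, 8)))
  for (s in names(object@stages))
    cat(sprintf("  %s: %d file(s), %d record(s)\n", s,
                length(object@stages[[s]]$files),
                object@stages[[s]]$nRecords))
  if (length(object@warnings))
    cat(sprintf("  %d warning(s)\n", length(object@warnings)))
})
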