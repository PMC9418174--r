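# File I/O: relaxation series CSV, cohort CSV, NIfTI volumes and masks,
# PNG/TIFF stain images and indexed-PNG annotations, fit tables.

#' Read relaxation series from CSV/TSV
#'
#' Expects columns `kind`, `time_ms`, `signal`, `excluded` (0/1), `roi`,
#' `animal`, `timepoint`. One [RelaxationSeries-class] is built per
#' animal x timepoint x roi group.
#'
#' @param path CSV (or TSV, by extension) file path.
#' @return data.frame with columns `animal`, `timepoint`, `roi` and a
#'   list-column `series` of [RelaxationSeries-class] objects.
#' @export
readRelaxationCSV <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("kind", "time_ms", "signal", "excluded", "roi", "animal",
            "timepoint")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  keys <- unique(d[, c("animal", "timepoint", "roi")])
  keys$series <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- d[d$animal == keys$animal[i] & d$timepoint == keys$timepoint[i] &
             d$roi == keys$roi[i], ]
    sub <- sub[order(sub$time_ms), ]
    RelaxationSeries(sub$time_ms, sub$signal, kind = sub$kind[1],
                     excluded = sub$excluded != 0, roiLabel = sub$roi[1])
  })
  keys
}

#' Write relaxation series to CSV
#'
#' Inverse of [readRelaxationCSV()].
#'
#' @param seriesTable data.frame with `animal`, `timepoint`, `roi` and a
#'   list-column `series`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeRelaxationCSV <- function(seriesTable, path) {
  rows <- lapply(seq_len(nrow(seriesTable)), function(i) {
    s <- seriesTable$series[[i]]
    data.frame(kind = relaxKind(s), time_ms = relaxTimes(s),
               signal = relaxSignals(s),
               excluded = as.integer(excludedPoints(s)),
               roi = seriesTable$roi[i], animal = seriesTable$animal[i],
               timepoint = seriesTable$timepoint[i])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a NIfTI volume
#' @param path NIfTI file (.nii or .nii.gz).
#' @return a [VolumeImage-class] with spacing from the header (mm).
#' @export
readVolumeNIfTI <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  VolumeImage(array(as.numeric(img), dim = dim(img)[1:3]), spacing = sp)
}

#' Read a NIfTI integer label mask
#' @param path NIfTI file.
#' @param organs named integer vector (organ name -> label id).
#' @return a [LabelMask-class].
#' @export
readLabelMaskNIfTI <- function(path, organs = integer(0)) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- array(as.integer(round(as.numeric(img))), dim = dim(img)[1:3])
  LabelMask(arr, spacing = sp, organs = organs)
}

#' Write a volume or mask to NIfTI
#' @param x a [VolumeImage-class] or [LabelMask-class].
#' @param path output path (.nii.gz).
#' @return the path, invisibly.
#' @export
writeNIfTI <- function(x, path) {
  img <- RNifti::asNifti(voxelData(x))
  RNifti::pixdim(img) <- voxelSpacing(x)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a stained-slide image (PNG or TIFF)
#' @param path image file; 8/16-bit RGB (an alpha channel is dropped,
#'   grayscale replicated).
#' @param pixelSize micrometres per pixel (optional metadata).
#' @param slideId slide identifier (defaults to the file name).
#' @return a [StainImage-class].
#' @export
readStainImage <- function(path, pixelSize = NA_real_,
                           slideId = basename(path)) {
  px <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  StainImage(px, pixelSize = pixelSize, slideId = slideId)
}

#' Write a stained-slide image to PNG
#' @param image a [StainImage-class].
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
writeStainImage <- function(image, path) {
  png::writePNG(pixelData(image), path)
  invisible(path)
}

#' Read an indexed-PNG annotation mask
#'
#' Annotation convention: 0 = unlabelled, 1 = negative, 2 = positive,
#' stored as a grayscale PNG with values 0, 1/255, 2/255.
#'
#' @param path PNG path.
#' @return integer matrix for [trainPixelModel()].
#' @export
readAnnotationPNG <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  ann <- matrix(as.integer(round(px * 255)), nrow(px), ncol(px))
  .assert(all(ann %in% 0:2),
          "annotation PNG must contain only the values 0, 1 and 2")
  ann
}

#' Write an annotation mask to indexed PNG
#' @param annotations integer 0/1/2 matrix.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
writeAnnotationPNG <- function(annotations, path) {
  .assert(all(annotations %in% 0:2), "annotations must be 0, 1 or 2")
  png::writePNG(annotations / 255, path)
  invisible(path)
}

#' Read a cohort table from CSV
#' @param path CSV with the [CohortTable-class] record columns.
#' @return a [CohortTable-class].
#' @export
readCohortCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"excluded" %in% names(d)) d$excluded <- FALSE
  d$excluded <- as.logical(d$excluded)
  if (!"reason" %in% names(d)) d$reason <- ""
  d$reason[is.na(d$reason)] <- ""
  CohortTable(d)
}

#' Write a cohort table to CSV
#' @param cohort a [CohortTable-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeCohortCSV <- function(cohort, path) {
  utils::write.csv(cohortData(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Flatten fit results to a table
#'
#' @param fits list of [T1Fit-class] or [T2Fit-class] objects.
#' @param animal,timepoint,tissue vectors parallel to `fits`.
#' @return data.frame with one row per fit: identifiers, the relaxation
#'   time (`T1_ms` or `T2_ms`), model parameters and diagnostics.
#' @export
fitTable <- function(fits, animal = NA_character_, timepoint = NA_real_,
                     tissue = NA_character_) {
  n <- length(fits)
  animal <- rep_len(animal, n); timepoint <- rep_len(timepoint, n)
  tissue <- rep_len(tissue, n)
  rows <- lapply(seq_len(n), function(i) {
    f <- fits[[i]]
    base <- data.frame(animal = animal[i], timepoint = timepoint[i],
                       tissue = tissue[i])
    if (is(f, "T1Fit"))
      cbind(base, data.frame(kind = "T1", T1_ms = f@t1, T2_ms = NA_real_,
                             a = f@a, b = f@b, t1Star = f@t1Star,
                             m0 = NA_real_, c = NA_real_,
                             residualRMS = f@residualRMS,
                             nPointsUsed = f@nPointsUsed,
                             converged = f@converged,
                             polarityFlipIndex = f@polarityFlipIndex))
    else
      cbind(base, data.frame(kind = "T2", T1_ms = NA_real_, T2_ms = f@t2,
                             a = NA_real_, b = NA_real_,
                             t1Star = NA_real_, m0 = f@m0, c = f@c,
                             residualRMS = f@residualRMS,
                             nPointsUsed = f@nPointsUsed,
                             converged = f@converged,
                             polarityFlipIndex = NA_integer_))
  })
  do.call(rbind, rows)
}
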