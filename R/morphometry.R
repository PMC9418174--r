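# Organ and tumor volumetry from label masks: voxel-count volumes,
# longitudinal trajectories with percent change, and onset detection.

#' Volume of one label in a mask
#'
#' Volume is the labelled voxel count times the voxel volume
#' (`prod(spacing)`), with no partial-volume weighting — matching how
#' semi-automatic segmentation tools report organ volumes. A label that
#' touches the grid boundary is flagged `truncated`, since the structure
#' may extend beyond the field of view and the reported volume covers the
#' in-grid part only.
#'
#' @param mask a [LabelMask-class], or an integer 3D array (then `spacing`
#'   is required).
#' @param labelId the label to measure; absent labels give a zero-volume
#'   record, not an error.
#' @param spacing mm per axis; taken from the mask when it is a
#'   [LabelMask-class].
#' @param organ organ name for the record; looked up in the mask's organ
#'   dictionary by default.
#' @param animal,timepoint identifiers carried into the record.
#' @return one-row data.frame: `animal`, `timepoint`, `organ`, `labelId`,
#'   `nVoxels`, `volumeMm3`, `truncated`.
#' @examples
#' m <- array(0L, c(10, 10, 10)); m[1:5, 2:6, 3:7] <- 1L
#' maskVolume(m, 1, spacing = c(0.22, 0.24, 0.25))
#' @export
maskVolume <- function(mask, labelId, spacing = NULL, organ = NULL,
                       animal = NA_character_, timepoint = NA_real_) {
  if (is(mask, "LabelMask")) {
    if (is.null(spacing)) spacing <- voxelSpacing(mask)
    if (is.null(organ)) {
      org <- organLabels(mask)
      hit <- names(org)[org == labelId]
      organ <- if (length(hit)) hit[1] else NA_character_
    }
    arr <- voxelData(mask)
  } else {
    .assert(is.array(arr <- mask) && length(dim(arr)) == 3L,
            "'mask' must be a LabelMask or a 3D array")
    .assert(!is.null(spacing), "'spacing' is required with an array mask")
  }
  .assert(length(spacing) == 3L && all(is.finite(spacing)) &&
          all(spacing > 0), "spacing must be 3 positive values (mm)")
  hit <- arr == labelId
  n <- sum(hit)
  truncated <- FALSE
  if (n > 0) {
    d <- dim(arr)
    truncated <- any(hit[1, , ]) || any(hit[d[1], , ]) ||
      any(hit[, 1, ]) || any(hit[, d[2], ]) ||
      any(hit[, , 1]) || any(hit[, , d[3]])
  }
  data.frame(animal = animal, timepoint = timepoint,
             organ = if (is.null(organ)) NA_character_ else organ,
             labelId = as.integer(labelId), nVoxels = as.integer(n),
             volumeMm3 = n * prod(spacing), truncated = truncated)
}

#' Longitudinal volume trajectory with per-interval percent change
#'
#' Orders one animal-and-organ's volume records by timepoint and reports
#' the percent change between consecutive timepoints,
#' `100 * (V_t - V_{t-1}) / V_{t-1}`. A step out of a zero volume has no
#' defined percent change and is flagged `"onset"` instead.
#'
#' @param volumes volumes in mm^3.
#' @param timepoints matching timepoints (months); duplicates are an error.
#' @param animal,organ identifiers carried through.
#' @return data.frame ordered by timepoint with columns `animal`, `organ`,
#'   `timepoint`, `volumeMm3`, `pctChange` (`NA` for the first record and
#'   after a zero volume) and `flag` (`""` or `"onset"`).
#' @examples
#' volumeTrajectory(c(100, 145), c(10, 12))$pctChange  # NA, +45
#' @export
volumeTrajectory <- function(volumes, timepoints = seq_along(volumes),
                             animal = NA_character_, organ = NA_character_) {
  .assert(length(volumes) >= 1, "at least one record is required")
  .assert(length(volumes) == length(timepoints),
          "'volumes' and 'timepoints' must have equal length")
  if (anyDuplicated(timepoints))
    stop("duplicate timepoints for one animal/organ", call. = FALSE)
  o <- order(timepoints)
  v <- as.numeric(volumes)[o]
  tp <- as.numeric(timepoints)[o]
  n <- length(v)
  pct <- rep(NA_real_, n)
  flag <- rep("", n)
  if (n > 1) {
    prev <- v[-n]
    ok <- prev > 0
    pct[-1][ok] <- 100 * (v[-1][ok] - prev[ok]) / prev[ok]
    flag[-1][!ok & v[-1] > 0] <- "onset"
  }
  data.frame(animal = animal, organ = organ, timepoint = tp,
             volumeMm3 = v, pctChange = pct, flag = flag)
}

#' Detect first threshold crossings in volume trajectories
#'
#' For each animal x organ, reports the earliest timepoint at which the
#' volume reaches `threshold`; series never reaching it are omitted. The
#' threshold is a user parameter: the minimum volume at which a lesion is
#' considered visible on the anatomical images.
#'
#' @param records data.frame with columns `animal`, `organ`, `timepoint`,
#'   `volumeMm3` (as produced by [volumeTrajectory()] or [maskVolume()]).
#' @param threshold detection threshold in mm^3 (> 0).
#' @return data.frame: `animal`, `organ`, `onsetTimepoint`,
#'   `onsetVolumeMm3`.
#' @examples
#' r <- data.frame(animal = "a", organ = "mammary",
#'                 timepoint = c(4, 6, 8, 10, 12),
#'                 volumeMm3 = c(0, 0, 0.5, 97, 259))
#' detectOnset(r, threshold = 0.4)  # onset at 8 months
#' @export
detectOnset <- function(records, threshold) {
  .assert(is.finite(threshold) && threshold > 0, "'threshold' must be > 0")
  need <- c("animal", "organ", "timepoint", "volumeMm3")
  .assert(all(need %in% names(records)),
          paste("records needs columns:", paste(need, collapse = ", ")))
  out <- list()
  for (key in unique(paste(records$animal, records$organ, sep = "\r"))) {
    sub <- records[paste(records$animal, records$organ, sep = "\r") == key, ]
    sub <- sub[order(sub$timepoint), ]
    hit <- which(sub$volumeMm3 >= threshold)[1]
    if (!is.na(hit))
      out[[length(out) + 1L]] <- data.frame(
        animal = sub$animal[1], organ = sub$organ[1],
        onsetTimepoint = sub$timepoint[hit],
        onsetVolumeMm3 = sub$volumeMm3[hit])
  }
  if (!length(out))
    return(data.frame(animal = character(0), organ = character(0),
                      onsetTimepoint = numeric(0),
                      onsetVolumeMm3 = numeric(0)))
  do.call(rbind, out)
}
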