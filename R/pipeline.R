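# End-to-end pipeline: synthetic or file inputs -> relaxometry fits ->
# volumetry -> iron quantification -> cohort report, with a single
# declarative config, per-stage logging and a provenance manifest.

#' Default pipeline run configuration
#'
#' One declarative list controls every stage; all tolerances and
#' thresholds surface here with their module defaults. In synthetic mode
#' the generators' ground-truth parameters double as the study
#' conditions: a 7-per-group 2 sex x 2 genotype cohort over months
#' 2–12, relaxometry from month 4 at SNR 50, a box + ellipsoid + tube
#' phantom, and a small panel of stained slides.
#'
#' @param seed integer seed (required in synthetic mode).
#' @param outputDir output directory.
#' @param mode `"synthetic"` or `"files"`.
#' @return a nested config list for [runPipeline()].
#' @export
defaultRunConfig <- function(seed = 1, outputDir = tempfile("mrimetry_run_"),
                             mode = "synthetic") {
  list(
    mode = mode,
    seed = seed,
    outputDir = outputDir,
    files = list(cohortCsv = NULL, relaxationCsv = NULL),
    cohort = list(nPerGroup = 7, timepoints = c(2, 4, 6, 8, 10, 12)),
    relaxometry = list(
      timepoints = c(4, 6, 8, 10, 12), snr = 50,
      t1A = 1000, t1BOverA = 1.96, nTI = 50,
      t2M0 = 1000, t2C = 30,
      tol = 1e-8, maxIter = 50, autoExclude = FALSE),
    phantom = list(gridShape = c(48, 48, 48),
                   spacing = c(0.22, 0.24, 0.25), noiseSigma = 10),
    histology = list(nSlides = 8, width = 64, height = 64,
                     jitterSD = 0.03, annotationsPerClass = 150,
                     fractions = NULL),
    stats = list(alpha = 0.05, gateMethod = "lilliefors", mtc = "none"),
    onsetThreshold = 0.4)
}

#' Validate a pipeline configuration
#'
#' @param config a config list as from [defaultRunConfig()].
#' @return character vector of violations, empty when the config is
#'   valid; each message names the offending field and the rule.
#' @export
validateConfig <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (!is.list(config)) return("config: must be a list")
  if (is.null(config$mode) ||
      !identical(config$mode %in% c("synthetic", "files"), TRUE))
    add("mode: must be exactly one of 'synthetic' or 'files'")
  if (length(config$mode) > 1)
    add("mode: exactly one input mode must be set")
  if (identical(config$mode, "synthetic") &&
      (is.null(config$seed) || !is.finite(config$seed)))
    add("seed: required in synthetic mode")
  if (identical(config$mode, "files")) {
    if (is.null(config$files$cohortCsv))
      add("files$cohortCsv: required in files mode")
  }
  if (is.null(config$outputDir) || !nzchar(config$outputDir))
    add("outputDir: must be a non-empty path")
  rx <- config$relaxometry
  if (!is.null(rx)) {
    if (!is.null(rx$snr) && (!is.finite(rx$snr) || rx$snr <= 0))
      add("relaxometry$snr: must be > 0")
    if (!is.null(rx$tol) && (!is.finite(rx$tol) || rx$tol <= 0))
      add("relaxometry$tol: must be > 0")
    if (!is.null(rx$maxIter) && rx$maxIter < 0)
      add("relaxometry$maxIter: must be >= 0")
  }
  if (!is.null(config$phantom$noiseSigma) &&
      (!is.finite(config$phantom$noiseSigma) ||
       config$phantom$noiseSigma < 0))
    add("phantom$noiseSigma: must be >= 0")
  if (!is.null(config$histology$jitterSD) && config$histology$jitterSD < 0)
    add("histology$jitterSD: must be >= 0")
  if (!is.null(config$cohort$nPerGroup) && config$cohort$nPerGroup < 2)
    add("cohort$nPerGroup: must be >= 2")
  if (!is.null(config$onsetThreshold) && config$onsetThreshold <= 0)
    add("onsetThreshold: must be > 0")
  v
}

#' Read a run configuration from YAML or JSON
#' @param path configuration file (.yaml/.yml or .json); fields merge
#'   over [defaultRunConfig()].
#' @return config list.
#' @export
readRunConfig <- function(path) {
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path,
                                                  simplifyVector = TRUE)
  base <- defaultRunConfig()
  merge2 <- function(a, b) {
    for (nm in names(b))
      a[[nm]] <- if (is.list(b[[nm]]) && is.list(a[[nm]]))
        merge2(a[[nm]], b[[nm]]) else b[[nm]]
    a
  }
  merge2(base, user)
}

# hash the analysis-relevant config; the output location does not alter
# the analysis, so two runs of one config into different directories
# share a hash (and hence a manifest)
.configHash <- function(config) {
  config$outputDir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

.stageFiles <- function(paths) lapply(paths, function(p)
  list(path = basename(p), md5 = unname(tools::md5sum(p))))

#' Run the full analysis pipeline
#'
#' Executes the stages in order — inputs (synthetic generation or file
#' loading), relaxometry fitting, morphometry, iron histomorphometry,
#' cohort statistics — writing per-stage CSV outputs, a human-readable
#' report and a provenance manifest (`manifest.json`) into the output
#' directory. Identical config and seed give byte-identical outputs. Any
#' stage failure aborts the run after writing a manifest of the stages
#' completed so far.
#'
#' @param config config list (see [defaultRunConfig()],
#'   [validateConfig()]).
#' @return a [RunManifest-class], invisibly the same object that is
#'   serialised to `manifest.json`.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  violations <- validateConfig(config)
  if (length(violations))
    stop("invalid configuration:\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  out <- config$outputDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  warningsLog <- character(0)
  stages <- list()
  seed <- as.integer(config$seed)

  # pre-flight: files mode inputs must be readable before any stage runs
  if (identical(config$mode, "files")) {
    paths <- Filter(Negate(is.null), config$files)
    bad <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(bad))
      stop("missing input file(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }

  manifestPath <- file.path(out, "manifest.json")
  finishManifest <- function() {
    man <- new("RunManifest", configHash = .configHash(config),
               version = as.character(utils::packageVersion("MRImetry")),
               outputDir = out, stages = stages, warnings = warningsLog)
    json <- jsonlite::toJSON(list(
      configHash = man@configHash, version = man@version,
      stages = stages, warnings = warningsLog),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
    writeLines(json, manifestPath)
    man
  }
  runStage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      warningsLog <<- c(warningsLog,
                        sprintf("stage '%s' failed: %s", name,
                                conditionMessage(res)))
      finishManifest()
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(res)),
           call. = FALSE)
    }
    stages[[name]] <<- list(files = .stageFiles(res$files),
                            nRecords = res$nRecords)
    res
  }

  ## stage 1: inputs
  cohort <- NULL
  inputs <- runStage("inputs", function() {
    if (identical(config$mode, "synthetic")) {
      cohort <<- simulateCohort(nPerGroup = config$cohort$nPerGroup,
                                timepoints = config$cohort$timepoints,
                                seed = seed)
    } else {
      cohort <<- readCohortCSV(config$files$cohortCsv)
    }
    p <- file.path(out, "cohort.csv")
    writeCohortCSV(cohort, p)
    nex <- sum(cohortData(cohort)$excluded)
    if (nex > 0)
      warningsLog <<- c(warningsLog,
                        sprintf("inputs: %d cohort record(s) excluded", nex))
    list(files = p, nRecords = nrow(cohortData(cohort)))
  })

  ## stage 2: relaxometry
  runStage("relaxometry", function() {
    rx <- config$relaxometry
    rec <- cohortData(cohort)
    fits <- list(); ids <- character(0); tps <- numeric(0)
    tis <- character(0)
    if (identical(config$mode, "synthetic")) {
      sub <- rec[rec$measurement %in% c("marrow_T1", "spleen_T2") &
                 rec$timepoint %in% rx$timepoints, ]
      sub <- sub[order(sub$animal, sub$timepoint, sub$measurement), ]
      for (i in seq_len(nrow(sub))) {
        sSeed <- (seed + 7L * i) %% .Machine$integer.max
        if (sub$measurement[i] == "marrow_T1") {
          a <- rx$t1A; b <- rx$t1A * rx$t1BOverA
          tr <- simulateIRSeries(defaultTISchedule(n = rx$nTI), a = a,
                                 b = b, t1 = sub$value[i],
                                 noiseSigma = a / rx$snr, seed = sSeed)
          f <- fitT1LookLocker(tr, tol = rx$tol, maxIter = rx$maxIter,
                               autoExclude = rx$autoExclude)
          tis <- c(tis, "marrow_L3")
        } else {
          tr <- simulateDecaySeries(defaultTESchedule(), m0 = rx$t2M0,
                                    t2 = sub$value[i], c0 = rx$t2C,
                                    noiseSigma = rx$t2M0 / rx$snr,
                                    seed = sSeed)
          f <- fitT2MonoExp(tr, tol = rx$tol, maxIter = rx$maxIter,
                            autoExclude = rx$autoExclude)
          tis <- c(tis, "spleen")
        }
        fits[[length(fits) + 1L]] <- f
        ids <- c(ids, sub$animal[i]); tps <- c(tps, sub$timepoint[i])
      }
    } else if (!is.null(config$files$relaxationCsv)) {
      tab <- readRelaxationCSV(config$files$relaxationCsv)
      for (i in seq_len(nrow(tab))) {
        s <- tab$series[[i]]
        f <- if (relaxKind(s) == "inversion_recovery")
          fitT1LookLocker(s, tol = rx$tol, maxIter = rx$maxIter,
                          autoExclude = rx$autoExclude)
        else fitT2MonoExp(s, tol = rx$tol, maxIter = rx$maxIter,
                          autoExclude = rx$autoExclude)
        fits[[length(fits) + 1L]] <- f
        ids <- c(ids, tab$animal[i]); tps <- c(tps, tab$timepoint[i])
        tis <- c(tis, tab$roi[i])
      }
    }
    files <- character(0)
    n <- 0L
    if (length(fits)) {
      ft <- fitTable(fits, animal = ids, timepoint = tps, tissue = tis)
      nbad <- sum(!ft$converged)
      if (nbad > 0)
        warningsLog <<- c(warningsLog,
                          sprintf("relaxometry: %d non-converged fit(s)",
                                  nbad))
      p <- file.path(out, "relaxometry_fits.csv")
      utils::write.csv(ft, p, row.names = FALSE)
      files <- p; n <- nrow(ft)
    }
    # internal-reference stability from the muscle reference measurement
    ref <- rec[rec$measurement == "muscle_T2" & !rec$excluded, ]
    if (nrow(ref)) {
      stab <- do.call(rbind, lapply(split(ref, ref$animal), function(d) {
        if (nrow(d) < 2) return(NULL)
        r <- stabilityReport(d$value, d$timepoint, animal = d$animal[1],
                             tissue = "muscle_T2")
        data.frame(animal = r@animal, tissue = r@tissue,
                   mean = r@meanValue, cov = r@cov,
                   maxAbsDeviationPct = max(abs(r@percentDeviation)))
      }))
      p2 <- file.path(out, "stability.csv")
      utils::write.csv(stab, p2, row.names = FALSE)
      files <- c(files, p2); n <- n + nrow(stab)
    }
    list(files = files, nRecords = n)
  })

  ## stage 3: morphometry
  runStage("morphometry", function() {
    ph <- config$phantom
    phantom <- simulatePhantom(
      shapes = list(
        phantomShape(1, "ellipsoid", ph$gridShape * ph$spacing / 2,
                     ph$gridShape * ph$spacing / 5),
        phantomShape(2, "box", ph$gridShape * ph$spacing * 0.22,
                     ph$gridShape * ph$spacing / 8),
        phantomShape(3, "tube", ph$gridShape * ph$spacing * 0.75,
                     c(min(ph$gridShape * ph$spacing) / 10,
                       ph$gridShape[3] * ph$spacing[3] / 4))),
      gridShape = ph$gridShape, spacing = ph$spacing,
      noiseSigma = ph$noiseSigma,
      organs = c(spleen = 1L, cecum = 2L, tumor = 3L),
      seed = (seed + 101L) %% .Machine$integer.max)
    vols <- do.call(rbind, lapply(phantom$truth$label, function(l)
      maskVolume(phantom$mask, l)))
    vols$analyticVolumeMm3 <- phantom$truth$analyticVolumeMm3
    if (any(vols$truncated))
      warningsLog <<- c(warningsLog,
                        "morphometry: label touches the grid boundary")
    p <- file.path(out, "phantom_volumes.csv")
    utils::write.csv(vols, p, row.names = FALSE)
    files <- p
    n <- nrow(vols)
    rec <- cohortData(cohort)
    tum <- rec[rec$measurement == "tumor_volume" & !rec$excluded, ]
    if (nrow(tum)) {
      traj <- do.call(rbind, lapply(split(tum, tum$animal), function(d)
        volumeTrajectory(d$value, d$timepoint, animal = d$animal[1],
                         organ = "tumor")))
      p2 <- file.path(out, "tumor_trajectories.csv")
      utils::write.csv(traj, p2, row.names = FALSE)
      onset <- detectOnset(traj, threshold = config$onsetThreshold)
      p3 <- file.path(out, "tumor_onsets.csv")
      utils::write.csv(onset, p3, row.names = FALSE)
      files <- c(files, p2, p3)
      n <- n + nrow(traj) + nrow(onset)
    }
    list(files = files, nRecords = n)
  })

  ## stage 4: iron histomorphometry
  runStage("histomorphometry", function() {
    hg <- config$histology
    fracs <- hg$fractions
    if (is.null(fracs))
      fracs <- seq(0.08, 0.22, length.out = hg$nSlides)
    rows <- list()
    for (i in seq_along(fracs)) {
      sSeed <- (seed + 211L * i) %% .Machine$integer.max
      sl <- simulateStainImage(hg$width, hg$height, fracs[i],
                               jitterSD = hg$jitterSD, seed = sSeed,
                               slideId = sprintf("slide_%02d", i))
      ann <- annotateFromTruth(sl$truth, n = hg$annotationsPerClass,
                               seed = sSeed)
      model <- trainPixelModel(sl$image, ann, seed = sSeed)
      res <- ironLoad(sl$image, model)
      res$trueFraction <- fracs[i]
      res$trainAccuracy <- model@trainAccuracy
      rows[[i]] <- res
    }
    iron <- do.call(rbind, rows)
    p <- file.path(out, "iron_load.csv")
    utils::write.csv(iron, p, row.names = FALSE)
    list(files = p, nRecords = nrow(iron))
  })

  ## stage 5: cohort statistics
  runStage("statistics", function() {
    st <- config$stats
    rep <- longitudinalReport(cohort, alpha = st$alpha,
                              gateMethod = st$gateMethod, mtc = st$mtc)
    p1 <- file.path(out, "report_summaries.csv")
    p2 <- file.path(out, "report_tests.csv")
    p3 <- file.path(out, "report.md")
    utils::write.csv(rep$summaries, p1, row.names = FALSE)
    utils::write.csv(rep$tests, p2, row.names = FALSE)
    writeLines(c("# Cohort statistics report", "", rep$text), p3)
    list(files = c(p1, p2, p3),
         nRecords = nrow(rep$summaries) + nrow(rep$tests))
  })

  invisible(finishManifest())
}
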