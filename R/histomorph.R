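# Stain histomorphometry: per-pixel feature extraction, supervised pixel
# classification, and iron load as percent positive area.

# Optical-density stain-separation vectors (unit norm): a Prussian-blue
# positive stain absorbs red/green strongly, a nuclear-red counterstain
# absorbs green/blue. Configurable; these defaults are generic, not
# calibrated to any particular scanner.
defaultStainVectors <- function()
  list(positive = c(0.70, 0.65, 0.29) / sqrt(sum(c(0.70, 0.65, 0.29)^2)),
       negative = c(0.21, 0.72, 0.66) / sqrt(sum(c(0.21, 0.72, 0.66)^2)))

#' Per-pixel features for stain classification
#'
#' Builds a feature matrix with one row per pixel: the raw RGB channels,
#' optionally two stain-separation channels (optical density projected on
#' fixed positive/negative stain vectors), and Gaussian-smoothed versions
#' of all of these at each requested scale. Deterministic.
#'
#' @param image a [StainImage-class] or a height x width x 3 array.
#' @param scales Gaussian smoothing sigmas in pixels (all > 0); an empty
#'   vector yields the unsmoothed channels only.
#' @param useDeconvolution add stain-separation channels (default `TRUE`).
#' @param stainVectors list with unit RGB optical-density vectors
#'   `positive` and `negative`.
#' @return numeric matrix (nPixels x nFeatures) with named columns; pixels
#'   are in column-major order of the height x width grid.
#' @export
extractPixelFeatures <- function(image, scales = c(1, 2),
                                 useDeconvolution = TRUE,
                                 stainVectors = defaultStainVectors()) {
  px <- if (is(image, "StainImage")) pixelData(image) else image
  .assert(length(dim(px)) == 3L && dim(px)[3] == 3L,
          "'image' must be an RGB array or StainImage")
  .assert(all(scales > 0), "all smoothing scales must be > 0")
  h <- dim(px)[1]; w <- dim(px)[2]
  chans <- list(R = px[, , 1], G = px[, , 2], B = px[, , 3])
  if (useDeconvolution) {
    od <- -log10(pmax(px, 1e-3))  # optical density per channel
    for (nm in names(stainVectors)) {
      v <- stainVectors[[nm]]
      chans[[paste0("od_", nm)]] <-
        od[, , 1] * v[1] + od[, , 2] * v[2] + od[, , 3] * v[3]
    }
  }
  out <- list()
  for (nm in names(chans)) out[[nm]] <- as.vector(chans[[nm]])
  # Gaussian brush must fit inside the image; clamp the support on tiny
  # images (odd radius <= min dimension)
  maxR <- min(h, w)
  if (maxR %% 2 == 0) maxR <- maxR - 1L
  for (sc in scales) {
    r <- min(2 * ceiling(3 * sc) + 1, maxR)
    for (nm in names(chans))
      out[[sprintf("%s_s%g", nm, sc)]] <-
        as.vector(EBImage::gblur(chans[[nm]], sigma = sc, radius = r))
  }
  mat <- do.call(cbind, out)
  rownames(mat) <- NULL
  mat
}

#' Train a supervised per-pixel stain classifier
#'
#' Trains a seedable classifier separating stain-positive from
#' stain-negative pixels from sparse manual annotations, on the features
#' of [extractPixelFeatures()]. A random forest is used when enough
#' labelled pixels are available; a linear discriminant is the fallback
#' for tiny training sets. Training accuracy on the labelled pixels is
#' reported in the model.
#'
#' @param image a [StainImage-class].
#' @param annotations integer matrix (height x width): 0 = unlabelled,
#'   1 = negative, 2 = positive. At least one pixel of each class is
#'   required.
#' @param seed integer seed (forest training).
#' @param scales,useDeconvolution,stainVectors feature controls, stored in
#'   the model and re-used at prediction time.
#' @param method `"auto"` (forest when >= `minForest` labelled pixels,
#'   else LDA), `"forest"`, or `"lda"`.
#' @param numTrees forest size.
#' @param minForest labelled-pixel count below which `"auto"` falls back
#'   to LDA.
#' @return a [PixelModel-class].
#' @export
trainPixelModel <- function(image, annotations, seed = 1,
                            scales = c(1, 2), useDeconvolution = TRUE,
                            stainVectors = defaultStainVectors(),
                            method = c("auto", "forest", "lda"),
                            numTrees = 100, minForest = 200) {
  method <- match.arg(method)
  px <- if (is(image, "StainImage")) pixelData(image) else image
  .assert(is.matrix(annotations) &&
          identical(dim(annotations), dim(px)[1:2]),
          "'annotations' must be a matrix matching the image size")
  .assert(all(annotations %in% 0:2),
          "annotation values must be 0 (unlabelled), 1 (negative), 2 (positive)")
  lab <- as.vector(annotations)
  sel <- lab > 0
  .assert(any(lab == 1) && any(lab == 2),
          "training needs at least one positive and one negative pixel")
  feats <- extractPixelFeatures(px, scales = scales,
                                useDeconvolution = useDeconvolution,
                                stainVectors = stainVectors)
  x <- feats[sel, , drop = FALSE]
  y <- factor(ifelse(lab[sel] == 2, "positive", "negative"),
              levels = c("negative", "positive"))
  # unlearnable: the two classes present identical feature rows throughout
  if (nrow(unique(x)) == 1L)
    stop("annotations are unlearnable: all labelled pixels have identical ",
         "features across both classes", call. = FALSE)
  # canonical row order: training is invariant to the order in which the
  # labelled pixels were supplied
  ord <- do.call(order, c(as.list(as.data.frame(x)), list(as.integer(y))))
  x <- x[ord, , drop = FALSE]
  y <- y[ord]
  if (method == "auto") method <- if (nrow(x) >= minForest) "forest" else "lda"
  if (method == "forest") {
    df <- data.frame(x, .class = y, check.names = FALSE)
    clf <- ranger::ranger(dependent.variable.name = ".class", data = df,
                          num.trees = numTrees, seed = as.integer(seed),
                          num.threads = 1, probability = FALSE)
    predTrain <- stats::predict(clf, data = df,
                                num.threads = 1)$predictions
  } else {
    # drop constant columns; lda cannot handle zero within-class variance
    keep <- apply(x, 2, function(col) stats::sd(col) > 0)
    if (!any(keep))
      stop("annotations are unlearnable: no feature varies across the ",
           "labelled pixels", call. = FALSE)
    clf <- MASS::lda(x[, keep, drop = FALSE], grouping = y)
    attr(clf, "keep") <- keep
    predTrain <- stats::predict(clf, x[, keep, drop = FALSE])$class
  }
  acc <- mean(predTrain == y)
  new("PixelModel", classifier = clf, method = method,
      featureSpec = list(scales = scales,
                         useDeconvolution = useDeconvolution,
                         stainVectors = stainVectors),
      classes = c("negative", "positive"), trainAccuracy = acc,
      meta = list(slideId = if (is(image, "StainImage")) slideId(image)
                            else "", nLabeled = nrow(x),
                  seed = as.integer(seed)))
}

#' Classify every pixel of a stained image
#'
#' @param model a trained [PixelModel-class].
#' @param image a [StainImage-class] or RGB array.
#' @return logical height x width matrix, `TRUE` = stain-positive.
#' @export
predictPixels <- function(model, image) {
  .assert(is(model, "PixelModel"), "'model' must be a PixelModel")
  px <- if (is(image, "StainImage")) pixelData(image) else image
  fs <- model@featureSpec
  feats <- extractPixelFeatures(px, scales = fs$scales,
                                useDeconvolution = fs$useDeconvolution,
                                stainVectors = fs$stainVectors)
  cls <- if (model@method == "forest") {
    stats::predict(model@classifier,
                   data = data.frame(feats, check.names = FALSE),
                   num.threads = 1)$predictions
  } else {
    keep <- attr(model@classifier, "keep")
    stats::predict(model@classifier,
                   feats[, keep, drop = FALSE])$class
  }
  matrix(cls == "positive", nrow = dim(px)[1], ncol = dim(px)[2])
}

#' Tissue mask by luminance threshold
#'
#' Marks as tissue every pixel darker than a luminance threshold,
#' excluding bright background (glass) from quantification.
#'
#' @param image a [StainImage-class] or RGB array.
#' @param threshold luminance cutoff in \[0, 1\]; pixels with luminance
#'   below it count as tissue.
#' @return logical height x width matrix.
#' @export
tissueMask <- function(image, threshold = 0.95) {
  px <- if (is(image, "StainImage")) pixelData(image) else image
  .luminance(px[, , 1], px[, , 2], px[, , 3]) < threshold
}

#' Iron load as percent positive area
#'
#' Classifies every tissue pixel with a trained model and reports the
#' stain-positive area as a percentage of the total tissue area
#' (background outside the tissue mask is excluded from both numerator
#' and denominator).
#'
#' @param image a [StainImage-class].
#' @param model a trained [PixelModel-class].
#' @param tissue logical tissue mask; defaults to [tissueMask()] of the
#'   image. Must contain at least one pixel.
#' @return data.frame: `slideId`, `positivePct`, `nPositive`, `nTissue`.
#' @export
ironLoad <- function(image, model, tissue = NULL) {
  px <- if (is(image, "StainImage")) pixelData(image) else image
  if (is.null(tissue)) tissue <- tissueMask(px)
  .assert(is.matrix(tissue) && identical(dim(tissue), dim(px)[1:2]),
          "'tissue' must be a logical matrix matching the image")
  .assert(any(tissue), "tissue mask is empty")
  pos <- predictPixels(model, px)
  nPos <- sum(pos & tissue)
  nTis <- sum(tissue)
  data.frame(slideId = if (is(image, "StainImage")) slideId(image) else "",
             positivePct = 100 * nPos / nTis,
             nPositive = as.integer(nPos), nTissue = as.integer(nTis))
}

#' Annotations from a ground-truth mask
#'
#' Utility to turn a known positive/negative mask into a sparse
#' annotation matrix by sampling `n` pixels per class — the synthetic
#' counterpart of manually annotating variably stained areas.
#'
#' @param truth logical matrix (`TRUE` = positive).
#' @param n pixels to label per class (capped at class size).
#' @param seed integer seed.
#' @return integer annotation matrix (0/1/2) for [trainPixelModel()].
#' @export
annotateFromTruth <- function(truth, n = 200, seed = 1) {
  .assert(is.matrix(truth) && is.logical(truth),
          "'truth' must be a logical matrix")
  .withSeed(seed, {
    ann <- matrix(0L, nrow(truth), ncol(truth))
    posIdx <- which(truth)
    negIdx <- which(!truth)
    if (length(posIdx))
      ann[posIdx[sample.int(length(posIdx), min(n, length(posIdx)))]] <- 2L
    if (length(negIdx))
      ann[negIdx[sample.int(length(negIdx), min(n, length(negIdx)))]] <- 1L
    ann
  })
}
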