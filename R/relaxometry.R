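# T1/T2 relaxometry: robust IRLS curve fitting of the Look-Locker
# inversion-recovery model and the offset mono-exponential decay model,
# ROI signal extraction, and longitudinal stability metrics.

#' Robust curve fitting by iteratively reweighted least squares
#'
#' Alternates a weighted nonlinear least-squares solve
#' (Levenberg–Marquardt) with Huber reweighting of the residuals until the
#' parameters change by less than `tol` (relative) or `maxIter` IRLS
#' iterations are reached. The robust residual scale is the median
#' absolute deviation times 1.4826; Huber weights are
#' `min(1, k * scale / |r|)` with tuning constant `k = 1.345`. With
#' `weightsRule = "unit"` the routine reduces to ordinary (unweighted)
#' least squares in a single solve.
#'
#' @param model prediction function `function(par, times)` returning the
#'   model signal at `times`.
#' @param start numeric start parameters.
#' @param times,signals the data.
#' @param weightsRule `"huber"` (default) or `"unit"`.
#' @param k Huber tuning constant (in robust-scale units).
#' @param tol relative parameter-change convergence tolerance.
#' @param maxIter maximum IRLS iterations; `0` returns `start` unchanged
#'   with `converged = FALSE`.
#' @param lower,upper optional box constraints passed to the inner solver.
#' @return list with `par`, `weights`, `residuals`, `residualRMS`
#'   (unweighted RMS), `iterations`, `converged` and `message`.
#' @examples
#' mod <- function(p, t) p[1] * exp(-t / p[2])
#' t <- seq(5, 100, by = 5); y <- mod(c(100, 30), t)
#' irlsFit(mod, c(80, 20), t, y)$par
#' @export
irlsFit <- function(model, start, times, signals,
                    weightsRule = c("huber", "unit"), k = 1.345,
                    tol = 1e-8, maxIter = 50, lower = NULL, upper = NULL) {
  weightsRule <- match.arg(weightsRule)
  .assert(all(is.finite(times)) && all(is.finite(signals)),
          "times and signals must be finite")
  .assert(length(times) == length(signals),
          "times and signals must have equal length")
  .assert(all(is.finite(start)), "start parameters must be finite")
  .assert(maxIter >= 0, "'maxIter' must be >= 0")
  par <- as.numeric(start)
  n <- length(signals)
  w <- rep(1, n)
  fail <- function(msg, it) list(
    par = par, weights = w, residuals = signals - tryCatch(
      model(par, times), error = function(e) rep(NA_real_, n)),
    residualRMS = NA_real_, iterations = it, converged = FALSE,
    message = msg)
  if (maxIter == 0) return(fail("maxIter = 0: start returned unfitted", 0L))

  # Levenberg-Marquardt, run twice: the restart resets the damping and
  # finishes off ill-conditioned problems the first pass stalls on
  solveWLS <- function(par0, w) {
    fn <- function(p) sqrt(w) * (signals - model(p, times))
    ctrl <- minpack.lm::nls.lm.control(maxiter = 500,
                                       ftol = 1e-15, ptol = 1e-15)
    res <- tryCatch(minpack.lm::nls.lm(par = par0, fn = fn, lower = lower,
                                       upper = upper, control = ctrl),
                    error = function(e) NULL)
    if (is.null(res) || any(!is.finite(res$par))) return(NULL)
    res2 <- tryCatch(minpack.lm::nls.lm(par = res$par, fn = fn,
                                        lower = lower, upper = upper,
                                        control = ctrl),
                     error = function(e) NULL)
    if (is.null(res2) || any(!is.finite(res2$par))) res$par else res2$par
  }

  huberW <- function(r) {
    s <- .robustScale(r)
    # residual scale negligible relative to the signal: an effectively
    # exact fit needs no reweighting (and reweighting on rounding noise
    # would only perturb it)
    if (s <= 1e-10 * sqrt(mean(signals^2))) return(rep(1, n))
    pmin(1, k * s / pmax(abs(r), 1e-300))
  }
  converged <- FALSE
  it <- 0L
  r <- signals - model(par, times)
  if (any(!is.finite(r))) return(fail("non-finite residuals at start", 0L))
  repeat {
    it <- it + 1L
    # weights come from the residuals of the current (initially: the
    # start's) parameters, so a robust start immediately downweights
    # gross outliers instead of letting an unweighted first solve jump
    # into their basin
    if (weightsRule == "huber") w <- huberW(r)
    newPar <- solveWLS(par, w)
    if (is.null(newPar)) return(fail("inner least-squares solve failed", it))
    r <- signals - model(newPar, times)
    if (any(!is.finite(r))) return(fail("non-finite residuals", it))
    delta <- max(abs(newPar - par) / pmax(abs(par), 1e-12))
    par <- newPar
    if (weightsRule == "unit") { converged <- TRUE; break }
    if (it > 1L && delta < tol) { converged <- TRUE; break }
    if (it >= maxIter) break
  }
  r <- signals - model(par, times)
  list(par = par, weights = w, residuals = r,
       residualRMS = sqrt(mean(r^2)), iterations = it,
       converged = converged, message = if (converged) "" else
         "maximum IRLS iterations reached")
}

.irModel <- function(p, t) p[1] - p[2] * exp(-t / p[3])
.decayModel <- function(p, t) p[1] * exp(-t / p[2]) + p[3]

# deterministic start for the IR model: a0 = max signal, b0 = a0 + |min|,
# T1*0 from the zero-crossing time (t_null / ln 2) or schedule midpoint
.irStart <- function(times, signals) {
  a0 <- max(signals)
  b0 <- a0 + abs(min(signals))
  cross <- which(signals[-length(signals)] < 0 & signals[-1] >= 0)[1]
  t1s0 <- if (!is.na(cross)) {
    s1 <- signals[cross]; s2 <- signals[cross + 1]
    tn <- times[cross] + (0 - s1) / (s2 - s1) * (times[cross + 1] - times[cross])
    tn / log(2)
  } else mean(range(times))
  c(a0, b0, max(t1s0, times[1]))
}

# deterministic start for the decay model: c0 near the late-echo floor,
# T2 from the median of pairwise log-amplitude slopes (a Theil-Sen
# estimate, immune to single gross outliers that would wreck a
# least-squares log-linear start), M0 from the median intercept
.decayStart <- function(times, signals) {
  c0 <- min(signals) * 0.999
  amp <- pmax(signals - c0, max(signals) * 1e-6)
  la <- log(amp)
  n <- length(times)
  ij <- utils::combn(n, 2)
  slopes <- (la[ij[2, ]] - la[ij[1, ]]) / (times[ij[2, ]] - times[ij[1, ]])
  slope <- stats::median(slopes)
  t20 <- if (is.finite(slope) && slope < 0) -1 / slope else mean(range(times))
  t20 <- max(t20, times[1] / 10)
  m00 <- exp(stats::median(la + times / t20))
  c(max(m00, max(signals) * 1e-3), t20, max(c0, 0))
}

#' Fit the Look-Locker inversion-recovery T1 model
#'
#' Fits \eqn{S(TI) = a - b e^{-TI/T1^*}} to the non-excluded points of an
#' inversion-recovery series by Huber IRLS and reports the corrected
#' longitudinal relaxation time \eqn{T1 = T1^* (b/a - 1)}.
#'
#' Magnitude data (all signals non-negative) lose the sign of the early,
#' still-inverted samples. Polarity is restored exhaustively: for every
#' candidate flip index j from 0 to (index of the signal minimum + 1), the
#' first j points are negated, the model is fitted, and the lowest-RMS
#' solution wins. Signed input (any negative signal) skips restoration.
#'
#' A solution with \eqn{b/a \le 1} implies a non-positive T1; it is
#' returned as-is with `converged = FALSE` rather than clamped.
#'
#' @param series a [RelaxationSeries-class] of kind `"inversion_recovery"`
#'   with at least 4 usable points.
#' @param tol,maxIter IRLS controls (see [irlsFit()]).
#' @param weightsRule `"huber"` or `"unit"` (plain least squares).
#' @param autoExclude if `TRUE`, after an initial fit, points with
#'   residuals beyond 4 robust standard deviations are flagged and the
#'   model is refitted once (off by default; exclusion flags normally come
#'   in with the data, mirroring a manual motion-rejection workflow).
#' @return a [T1Fit-class].
#' @examples
#' s <- simulateIRSeries(a = 1000, b = 1800, t1Star = 600, magnitude = FALSE)
#' t1Value(fitT1LookLocker(s))  # 600 * (1800/1000 - 1) = 480
#' @export
fitT1LookLocker <- function(series, tol = 1e-8, maxIter = 50,
                            weightsRule = c("huber", "unit"),
                            autoExclude = FALSE) {
  weightsRule <- match.arg(weightsRule)
  .assert(is(series, "RelaxationSeries"), "'series' must be a RelaxationSeries")
  .assert(series@kind == "inversion_recovery",
          "series kind must be 'inversion_recovery'")
  use <- !series@excluded
  .assert(sum(use) >= 4, "at least 4 non-excluded points are required")
  t <- series@times[use]
  s <- series@signals[use]
  n <- length(s)

  failFit <- function(msg) new("T1Fit", a = NA_real_, b = NA_real_,
    t1Star = NA_real_, t1 = NA_real_, residualRMS = NA_real_,
    nPointsUsed = as.integer(n), converged = FALSE,
    polarityFlipIndex = 0L, iterations = 0L, message = msg)
  if (diff(range(s)) == 0)
    return(failFit("all signals identical: model unidentifiable"))

  flips <- if (any(s < 0)) 0L else 0:min(n - 1L, which.min(s) + 1L)
  best <- NULL
  bestFlip <- 0L
  for (j in flips) {
    sj <- s
    if (j > 0) sj[1:j] <- -sj[1:j]
    fit <- irlsFit(.irModel, .irStart(t, sj), t, sj,
                   weightsRule = weightsRule, tol = tol, maxIter = maxIter,
                   lower = c(-Inf, -Inf, 1e-9))
    if (!is.finite(fit$residualRMS)) next
    if (is.null(best) || fit$residualRMS < best$residualRMS) {
      best <- fit; bestFlip <- j; bestSignals <- sj
    }
  }
  if (is.null(best)) return(failFit("all polarity-candidate fits failed"))

  if (autoExclude) {
    sc <- .robustScale(best$residuals)
    bad <- if (sc > 0) abs(best$residuals) > 4 * sc else rep(FALSE, n)
    if (any(bad) && sum(!bad) >= 4) {
      refit <- irlsFit(.irModel, best$par, t[!bad], bestSignals[!bad],
                       weightsRule = weightsRule, tol = tol,
                       maxIter = maxIter, lower = c(-Inf, -Inf, 1e-9))
      if (is.finite(refit$residualRMS)) { best <- refit; n <- sum(!bad) }
    }
  }

  a <- best$par[1]; b <- best$par[2]; t1Star <- best$par[3]
  t1 <- t1Star * (b / a - 1)
  degenerate <- !is.finite(t1) || a <= 0 || b / a <= 1
  new("T1Fit", a = a, b = b, t1Star = t1Star, t1 = t1,
      residualRMS = best$residualRMS, nPointsUsed = as.integer(n),
      converged = best$converged && !degenerate,
      polarityFlipIndex = as.integer(bestFlip),
      iterations = as.integer(best$iterations),
      message = if (degenerate)
        "degenerate solution: b/a <= 1 implies non-positive T1"
      else best$message)
}

#' Fit the offset mono-exponential T2 model
#'
#' Fits \eqn{S(TE) = M_0 e^{-TE/T2} + c} to a multi-echo decay series by
#' Huber IRLS. The first echo is always excluded before fitting,
#' regardless of the caller's exclusion flags, because the first echo of a
#' multi-echo spin-echo train is biased by stimulated-echo contributions.
#' The offset `c` absorbs the magnitude-image noise floor and is not
#' constrained to be non-negative.
#'
#' @param series a [RelaxationSeries-class] of kind `"echo_decay"` with at
#'   least 3 usable points after the first-echo exclusion.
#' @param tol,maxIter,weightsRule,autoExclude as in [fitT1LookLocker()].
#' @return a [T2Fit-class].
#' @examples
#' s <- simulateDecaySeries(m0 = 1000, t2 = 14, c0 = 50)
#' t2Value(fitT2MonoExp(s))
#' @export
fitT2MonoExp <- function(series, tol = 1e-8, maxIter = 50,
                         weightsRule = c("huber", "unit"),
                         autoExclude = FALSE) {
  weightsRule <- match.arg(weightsRule)
  .assert(is(series, "RelaxationSeries"), "'series' must be a RelaxationSeries")
  .assert(series@kind == "echo_decay", "series kind must be 'echo_decay'")
  use <- !series@excluded
  use[1] <- FALSE  # first echo always excluded
  .assert(sum(use) >= 3,
          "at least 3 non-excluded points after first-echo exclusion required")
  t <- series@times[use]
  s <- series@signals[use]
  n <- length(s)

  failFit <- function(msg) new("T2Fit", m0 = NA_real_, t2 = NA_real_,
    c = NA_real_, residualRMS = NA_real_, nPointsUsed = as.integer(n),
    converged = FALSE, iterations = 0L, message = msg)
  if (diff(range(s)) == 0)
    return(failFit("all signals identical: model unidentifiable"))

  fit <- irlsFit(.decayModel, .decayStart(t, s), t, s,
                 weightsRule = weightsRule, tol = tol, maxIter = maxIter,
                 lower = c(1e-12, 1e-9, -Inf))
  if (!is.finite(fit$residualRMS))
    return(failFit(fit$message))

  if (autoExclude) {
    sc <- .robustScale(fit$residuals)
    bad <- if (sc > 0) abs(fit$residuals) > 4 * sc else rep(FALSE, n)
    if (any(bad) && sum(!bad) >= 3) {
      refit <- irlsFit(.decayModel, fit$par, t[!bad], s[!bad],
                       weightsRule = weightsRule, tol = tol,
                       maxIter = maxIter, lower = c(1e-12, 1e-9, -Inf))
      if (is.finite(refit$residualRMS)) { fit <- refit; n <- sum(!bad) }
    }
  }

  # polish: at the final weights, (M0, c) are linear in the model given
  # T2, so a profiled 1-D refinement plus a Levenberg-Marquardt restart
  # finishes off ill-conditioned cases (T2 comparable to the schedule
  # length) that stall the main solver
  polished <- .profileT2(t, s, fit$weights, fit$par)
  refit <- irlsFit(.decayModel, polished, t, s, weightsRule = weightsRule,
                   tol = tol, maxIter = max(maxIter, 1),
                   lower = c(1e-12, 1e-9, -Inf))
  if (is.finite(refit$residualRMS) &&
      refit$residualRMS <= fit$residualRMS) fit <- refit

  m0 <- fit$par[1]; t2 <- fit$par[2]; c0 <- fit$par[3]
  degenerate <- !is.finite(t2) || t2 <= 0 || m0 <= 0
  new("T2Fit", m0 = m0, t2 = t2, c = c0, residualRMS = fit$residualRMS,
      nPointsUsed = as.integer(n),
      converged = fit$converged && !degenerate,
      iterations = as.integer(fit$iterations),
      message = if (degenerate) "degenerate solution (T2 or M0 <= 0)"
                else fit$message)
}

# weighted profiled refinement of the decay fit: minimise over T2 with
# (M0, c) solved by weighted linear least squares; keep only if it does
# not increase the weighted SSE
.profileT2 <- function(t, s, w, par) {
  wsse <- function(p) sum(w * (s - .decayModel(p, t))^2)
  obj <- function(tau) {
    X <- cbind(exp(-t / tau), 1)
    co <- tryCatch(stats::lm.wfit(X, s, w)$coefficients,
                   error = function(e) c(NA, NA))
    if (any(!is.finite(co))) return(1e300)
    sum(w * (s - X %*% co)^2)
  }
  t2 <- par[2]
  opt <- tryCatch(stats::optimize(obj, interval = c(t2 / 3, t2 * 3),
                                  tol = .Machine$double.eps^0.5 * t2),
                  error = function(e) NULL)
  if (is.null(opt)) return(par)
  tau <- opt$minimum
  co <- stats::lm.wfit(cbind(exp(-t / tau), 1), s, w)$coefficients
  cand <- c(unname(co[1]), tau, unname(co[2]))
  if (all(is.finite(cand)) && wsse(cand) <= wsse(par)) cand else par
}

#' Extract a mean-signal relaxation series from an image stack
#'
#' Averages the voxel values inside one ROI across an ordered stack of
#' volumes acquired at the given sample times. A `"background"` ROI placed
#' in air additionally yields a Rician noise-scale estimate: the mean of a
#' pure-noise magnitude signal is Rayleigh with mean
#' \eqn{\sigma\sqrt{\pi/2}}, so \eqn{\hat\sigma =} mean / \eqn{\sqrt{\pi/2}}.
#'
#' @param stack list of [VolumeImage-class] volumes on a common grid, one
#'   per sample time.
#' @param roi logical array on the same grid (`TRUE` = ROI voxel), or a
#'   [LabelMask-class] together with `labelId`.
#' @param times sample times in ms, one per volume.
#' @param kind `"inversion_recovery"` or `"echo_decay"`.
#' @param roiName ROI name; `"background"` triggers the noise estimate.
#' @param labelId label id when `roi` is a [LabelMask-class].
#' @return a [RelaxationSeries-class]; for a background ROI the estimated
#'   sigma is stored in `backgroundSigma` (averaged over timepoints).
#' @export
roiMeanSeries <- function(stack, roi, times,
                          kind = c("inversion_recovery", "echo_decay"),
                          roiName = "", labelId = NULL) {
  kind <- match.arg(kind)
  .assert(is.list(stack) && length(stack) == length(times),
          "'stack' must be a list of volumes, one per sample time")
  if (is(roi, "LabelMask")) {
    .assert(!is.null(labelId), "'labelId' is required with a LabelMask roi")
    roi <- voxelData(roi) == labelId
  }
  .assert(is.array(roi) && is.logical(roi), "'roi' must be a logical array")
  .assert(any(roi), "ROI is empty")
  dims <- dim(roi)
  for (v in stack) {
    .assert(is(v, "VolumeImage"), "stack elements must be VolumeImage objects")
    .assert(identical(dim(voxelData(v)), dims),
            "all volumes and the ROI must share one grid")
  }
  vals <- vapply(stack, function(v) mean(voxelData(v)[roi]), numeric(1))
  bg <- NA_real_
  if (identical(roiName, "background"))
    bg <- mean(vals) / sqrt(pi / 2)
  RelaxationSeries(times, vals, kind = kind, roiLabel = roiName,
                   backgroundSigma = bg)
}

#' Longitudinal stability of an internal reference tissue
#'
#' For one animal's serial measurements of a reference tissue, computes
#' the per-timepoint percent deviation from the animal's mean,
#' `100 * (value - mean) / mean`, and the coefficient of variation,
#' `100 * sd / mean`. Used to verify the serial stability of relaxometry
#' against a tissue not expected to change.
#'
#' @param values measurement values, one per timepoint (>= 2, mean > 0).
#' @param timepoints timepoints (months); defaults to 1..n.
#' @param animal,tissue identifiers.
#' @return a [StabilityReport-class].
#' @examples
#' stabilityReport(c(98, 102))  # deviations -2%, +2%; CoV ~ 2.83%
#' @export
stabilityReport <- function(values, timepoints = seq_along(values),
                            animal = "", tissue = "") {
  .assert(length(values) >= 2, "at least 2 timepoints are required")
  .assert(length(values) == length(timepoints),
          "'values' and 'timepoints' must have equal length")
  .assert(all(is.finite(values)), "values must be finite")
  m <- mean(values)
  .assert(m > 0, "mean value must be > 0")
  new("StabilityReport", animal = as.character(animal),
      tissue = as.character(tissue), timepoints = as.numeric(timepoints),
      values = as.numeric(values), meanValue = m,
      percentDeviation = 100 * (values - m) / m,
      cov = 100 * stats::sd(values) / m)
}
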