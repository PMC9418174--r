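# Brute-force reference fits: dense grid search plus Nelder-Mead
# refinement of the plain least-squares objective. Deliberately
# independent of the IRLS path; used to validate it.

#' Grid-search reference fit of the inversion-recovery model
#'
#' Minimises the unweighted sum of squares of
#' \eqn{S(TI) = a - b e^{-TI/T1^*}} over a dense parameter grid and
#' refines the best grid point with Nelder-Mead. Slow by design; intended
#' as an independent reference for validating the IRLS fitter, not for
#' production use. Expects signed signals (apply polarity restoration
#' before calling on magnitude data).
#'
#' @param times,signals the signed data.
#' @param nGrid grid points per parameter dimension.
#' @param aRange,bRange,t1StarRange search ranges; defaults are data-driven.
#' @return list with `par` (a, b, t1Star), `t1` and `sse`.
#' @export
gridFitT1 <- function(times, signals, nGrid = 25,
                      aRange = NULL, bRange = NULL, t1StarRange = NULL) {
  .assert(length(times) == length(signals) && length(times) >= 4,
          "need >= 4 (time, signal) pairs")
  smax <- max(abs(signals))
  if (is.null(aRange)) aRange <- c(0.2, 2) * max(smax, 1e-9)
  if (is.null(bRange)) bRange <- c(0.2, 4) * max(smax, 1e-9)
  if (is.null(t1StarRange)) t1StarRange <- c(times[1] / 2, max(times) * 2)
  sse <- function(p) sum((signals - (p[1] - p[2] * exp(-times / p[3])))^2)
  aG <- seq(aRange[1], aRange[2], length.out = nGrid)
  bG <- seq(bRange[1], bRange[2], length.out = nGrid)
  tG <- exp(seq(log(t1StarRange[1]), log(t1StarRange[2]),
                length.out = nGrid))
  best <- NULL
  for (t1s in tG) {
    # for fixed T1*, (a, b) enter linearly: profile them out exactly
    x <- exp(-times / t1s)
    co <- tryCatch(unname(stats::lm.fit(cbind(1, -x), signals)$coefficients),
                   error = function(e) c(NA, NA))
    cand <- rbind(expand.grid(a = aG, b = bG),
                  data.frame(a = co[1], b = co[2]))
    for (i in seq_len(nrow(cand))) {
      p <- c(cand$a[i], cand$b[i], t1s)
      if (any(!is.finite(p))) next
      v <- sse(p)
      if (is.null(best) || v < best$sse) best <- list(par = p, sse = v)
    }
  }
  ref <- stats::optim(best$par, sse, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  ref <- stats::optim(ref$par, sse, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  p <- ref$par
  list(par = c(a = p[1], b = p[2], t1Star = p[3]),
       t1 = p[3] * (p[2] / p[1] - 1), sse = ref$value)
}

#' Grid-search reference fit of the offset decay model
#'
#' Brute-force least-squares reference for
#' \eqn{S(TE) = M_0 e^{-TE/T2} + c}: dense T2 grid with (M0, c) profiled
#' out by linear regression at each grid point, then Nelder-Mead
#' refinement. Echo exclusion is the caller's responsibility.
#'
#' @param times,signals the data (already excluding any unwanted echoes).
#' @param nGrid T2 grid size.
#' @param t2Range search range in ms; default data-driven.
#' @return list with `par` (m0, t2, c) and `sse`.
#' @export
gridFitT2 <- function(times, signals, nGrid = 400, t2Range = NULL) {
  .assert(length(times) == length(signals) && length(times) >= 3,
          "need >= 3 (time, signal) pairs")
  if (is.null(t2Range)) t2Range <- c(times[1] / 5, max(times) * 3)
  sse <- function(p) sum((signals - (p[1] * exp(-times / p[2]) + p[3]))^2)
  tG <- exp(seq(log(t2Range[1]), log(t2Range[2]), length.out = nGrid))
  best <- NULL
  for (t2 in tG) {
    x <- exp(-times / t2)
    co <- tryCatch(unname(stats::lm.fit(cbind(x, 1), signals)$coefficients),
                   error = function(e) c(NA, NA))
    p <- c(co[1], t2, co[2])
    if (any(!is.finite(p))) next
    v <- sse(p)
    if (is.null(best) || v < best$sse) best <- list(par = p, sse = v)
  }
  ref <- stats::optim(best$par, sse, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  p <- ref$par
  list(par = c(m0 = p[1], t2 = p[2], c = p[3]), sse = ref$value)
}
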