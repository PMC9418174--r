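# internal helpers shared across modules

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. seed = NULL uses the current stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Rician perturbation of a noiseless magnitude signal: magnitude of a complex
# Gaussian with the true signal on the real axis and sd = sigma per component.
.riceNoise <- function(signal, sigma) {
  n <- length(signal)
  sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

.assert <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

.strictlyIncreasing <- function(x) length(x) < 2L || all(diff(x) > 0)

# significance stars at the thresholds 0.05 / 0.01 / 0.001
starsForP <- function(p) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  out <- ifelse(p <= 0.001, "***",
         ifelse(p <= 0.01, "**",
         ifelse(p <= 0.05, "*", "ns")))
  out[is.na(p)] <- NA_character_
  out
}

# robust residual scale: median absolute deviation about the median, scaled
# by 1.4826 so it estimates sigma for Gaussian residuals
.robustScale <- function(r) 1.4826 * stats::median(abs(r - stats::median(r)))

.luminance <- function(r, g, b) 0.299 * r + 0.587 * g + 0.114 * b
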