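#' @importFrom rlang .data abort warn
#' @importFrom stats rnorm sd var t.test lm resid pt fft quantile setNames
#' @importFrom utils head tail
NULL

# Run code with a private RNG stream, restoring the caller's stream after.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Derive a child seed < 2^31 from a parent seed and an index.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483587) + 1L
}

# Symmetric (zero-phase) Hann taper.
hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

# Symmetric-eigen pseudo-inverse; keeps the result exactly symmetric.
pinv_sym <- function(A, tol = 1e-12) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values), .Machine$double.eps)
  if (!any(keep)) return(matrix(0, nrow(A), ncol(A)))
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (t(V) / e$values[keep])
}

# Principal square root of a symmetric positive-(semi)definite matrix.
sqrtm_spd <- function(A, context = "matrix") {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  if (max(e$values) <= 0) {
    abort(sprintf("square root undefined: %s is not positive definite", context))
  }
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
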