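#' Canonical EEG frequency bands
#'
#' The seven fixed bands used throughout the pipeline: delta (2-4 Hz), theta
#' (4-8 Hz), alpha 1 (8-10.5 Hz), alpha 2 (10.5-13 Hz), beta 1 (13-20 Hz),
#' beta 2 (20-30 Hz) and gamma (30-40 Hz). Bands are contiguous and share
#' their boundary frequency bin: on the 0.5 Hz analysis grid the bin at
#' 4 Hz belongs to both delta and theta, the bin at 10.5 Hz to both alpha 1
#' and alpha 2, and so on. This mirrors the convention that neighbouring
#' rhythms overlap at their borders.
#'
#' @return A tibble with columns `band`, `f_lo` and `f_hi` (Hz), ordered from
#'   delta to gamma.
#' @examples
#' band_scheme()
#' @export
band_scheme <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha1", "alpha2", "beta1", "beta2", "gamma"),
    f_lo = c(2, 4, 8, 10.5, 13, 20, 30),
    f_hi = c(4, 8, 10.5, 13, 20, 30, 40)
  )
}

#' @rdname band_scheme
#' @export
band_names <- function() band_scheme()$band

# Indices of the frequency bins belonging to a band (boundary inclusive).
band_bins <- function(freqs, f_lo, f_hi, tol = 1e-9) {
  which(freqs >= f_lo - tol & freqs <= f_hi + tol)
}

validate_band_scheme <- function(scheme) {
  stopifnot(is.data.frame(scheme), all(c("band", "f_lo", "f_hi") %in% names(scheme)))
  if (any(scheme$f_lo >= scheme$f_hi)) abort("band scheme: f_lo must be < f_hi")
  if (nrow(scheme) > 1 && any(abs(scheme$f_hi[-nrow(scheme)] - scheme$f_lo[-1]) > 1e-9)) {
    abort("band scheme: bands must be contiguous (each f_hi equals the next f_lo)")
  }
  invisible(scheme)
}
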