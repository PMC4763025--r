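# Windowed one-sided FFT coefficients of every accepted epoch, scaled so
# that |coef|^2 is the one-sided power spectral density contribution of the
# epoch (Hann taper, window power compensation, no segment overlap). Shared
# by the auto- and cross-spectral estimators and the source projections.
epoch_fft <- function(es, window = "hanning") {
  if (!identical(window, "hanning")) abort("only the Hanning window is supported")
  eps <- accepted_epochs(es)
  n_sig <- dim(eps)[1]; n_samp <- dim(eps)[2]; n_ep <- dim(eps)[3]
  w <- hann_window(n_samp)
  n_bins <- n_samp %/% 2 + 1L
  freqs <- (seq_len(n_bins) - 1L) * es$fs / n_samp
  # one-sided scaling: sqrt(2/(fs*sum(w^2))) with no doubling at DC/Nyquist
  scale <- sqrt(2 / (es$fs * sum(w^2)))
  onesided <- rep(1, n_bins)
  onesided[1L] <- 1 / sqrt(2)
  if (n_samp %% 2 == 0L) onesided[n_bins] <- 1 / sqrt(2)
  coef <- array(0i, dim = c(n_sig, n_bins, n_ep))
  for (k in seq_len(n_ep)) {
    x <- eps[, , k, drop = FALSE]
    dim(x) <- c(n_sig, n_samp)
    xf <- t(stats::mvfft(t(x * rep(w, each = n_sig))))[, seq_len(n_bins), drop = FALSE]
    coef[, , k] <- xf * rep(scale * onesided, each = n_sig)
  }
  list(coef = coef, freqs = freqs, n_epochs = n_ep,
       labels = es$labels %||% paste0("sig", seq_len(n_sig)), fs = es$fs)
}

new_spectra <- function(values, freqs, n_epochs, labels = rownames(values), unit = "uV^2/Hz") {
  values <- as.matrix(values)
  if (is.null(labels)) labels <- paste0("sig", seq_len(nrow(values)))
  rownames(values) <- labels
  structure(list(values = values, freqs = freqs, n_epochs = n_epochs,
                 labels = labels, unit = unit),
            class = "eeg_spectra")
}

#' @export
print.eeg_spectra <- function(x, ...) {
  cat(sprintf("<eeg_spectra> %d signals x %d bins (%g-%g Hz, df=%g), %d epochs averaged\n",
              nrow(x$values), length(x$freqs), min(x$freqs), max(x$freqs),
              x$freqs[2] - x$freqs[1], x$n_epochs))
  invisible(x)
}

#' Welch power spectral density of an epoch set
#'
#' Per accepted 2-s epoch, the Hann-tapered full-epoch periodogram with
#' window power compensation; the output is the average over accepted
#' epochs. The 2-s artifact-screened epochs are themselves the Welch
#' segments (no sub-segmentation, no overlap), which is what yields the
#' 0.5 Hz frequency resolution of the analysis grid natively. Rejected
#' epochs are excluded.
#'
#' The estimator satisfies a Parseval identity: `sum(PSD) * df` equals the
#' window-compensated signal variance, so a unit-amplitude sinusoid carries
#' total power 0.5 uV^2.
#'
#' @param es an `eeg_epochs` object with at least one accepted epoch and
#'   2-s epochs.
#' @param window taper name; only `"hanning"` is implemented.
#' @return An `eeg_spectra` object: signals x frequency-bins power density on
#'   a 0.5 Hz grid from 0 to the Nyquist frequency.
#' @export
welch_psd <- function(es, window = "hanning") {
  stopifnot(inherits(es, "eeg_epochs"))
  if (abs(es$epoch_length - 2) > 1e-9) {
    abort("welch_psd requires 2-s epochs (the 0.5 Hz resolution contract)")
  }
  ef <- epoch_fft(es, window)
  pow <- matrix(0, dim(ef$coef)[1], dim(ef$coef)[2])
  for (k in seq_len(ef$n_epochs)) pow <- pow + abs(ef$coef[, , k])^2
  new_spectra(pow / ef$n_epochs, ef$freqs, ef$n_epochs, labels = ef$labels)
}

#' Band powers under the inclusive boundary-bin rule
#'
#' Band power is the mean of the PSD values over the band's frequency bins,
#' where a bin belongs to a band when `f_lo <= bin <= f_hi`: boundary bins
#' (4, 8, 10.5, 13, 20, 30 Hz) contribute to both adjacent bands. The mean
#' (rather than the sum) makes bands of unequal width comparable as power
#' densities.
#'
#' @param sp an `eeg_spectra` object covering the requested bands.
#' @param scheme a band scheme tibble, default [band_scheme()].
#' @return A tibble with columns `signal`, `band`, `power` (long format, one
#'   row per signal x band).
#' @export
band_power <- function(sp, scheme = band_scheme()) {
  stopifnot(inherits(sp, "eeg_spectra"))
  validate_band_scheme(scheme)
  out <- purrr::pmap_dfr(scheme, function(band, f_lo, f_hi) {
    if (f_lo < min(sp$freqs) - 1e-9 || f_hi > max(sp$freqs) + 1e-9) {
      abort(sprintf("band %s (%g-%g Hz) outside spectral range (%g-%g Hz)",
                    band, f_lo, f_hi, min(sp$freqs), max(sp$freqs)))
    }
    idx <- band_bins(sp$freqs, f_lo, f_hi)
    tibble::tibble(signal = sp$labels, band = band,
                   power = rowMeans(sp$values[, idx, drop = FALSE]))
  })
  out$band <- factor(out$band, levels = scheme$band)
  dplyr::arrange(out, .data$band, match(.data$signal, sp$labels))
}

#' Individual alpha frequency (IAF)
#'
#' The frequency of the strongest power in the extended alpha range
#' (7-14 Hz, inclusive), on the PSD averaged across all signals. Ties are
#' broken by the lowest frequency, making the detector deterministic.
#' The result is invariant to overall spectral scaling.
#'
#' @param sp an `eeg_spectra` object covering 7-14 Hz.
#' @param f_range search range in Hz, default `c(7, 14)`.
#' @return The IAF in Hz (a bin frequency on the 0.5 Hz grid).
#' @export
detect_iaf <- function(sp, f_range = c(7, 14)) {
  stopifnot(inherits(sp, "eeg_spectra"))
  idx <- band_bins(sp$freqs, f_range[1], f_range[2])
  if (length(idx) == 0L) abort("spectrum does not cover the 7-14 Hz search range")
  m <- colMeans(sp$values[, idx, drop = FALSE])
  if (!all(is.finite(m))) abort("non-finite PSD values in the IAF search range")
  sp$freqs[idx][which.max(m)]
}
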