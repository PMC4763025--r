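#' Welch cross-spectral matrix
#'
#' Tapered FFT outer products per accepted epoch, averaged across epochs,
#' with conjugate symmetry enforced. At least two accepted epochs are
#' required (a single epoch makes coherence trivially 1).
#'
#' @param x an `eeg_epochs` (channel-level) or `source_series` (voxel-level)
#'   object.
#' @param window taper; only `"hanning"`.
#' @return Object of class `cross_spectrum`: complex array
#'   signals x signals x bins, frequencies, epoch count.
#' @export
cross_spectrum <- function(x, window = "hanning") {
  if (inherits(x, "eeg_epochs")) {
    ef <- epoch_fft(x, window)
    coef <- ef$coef; freqs <- ef$freqs; n_ep <- ef$n_epochs; labels <- ef$labels
  } else if (inherits(x, "source_series")) {
    coef <- x$coef; freqs <- x$freqs; n_ep <- x$n_epochs; labels <- x$labels
  } else {
    abort("cross_spectrum expects an eeg_epochs or source_series object")
  }
  if (n_ep < 2L) abort("cross-spectrum needs at least 2 accepted epochs")
  ns <- dim(coef)[1]; nb <- dim(coef)[2]
  S <- array(0i, dim = c(ns, ns, nb))
  for (b in seq_len(nb)) {
    Xe <- coef[, b, , drop = FALSE]
    dim(Xe) <- c(ns, n_ep)
    Sb <- (Xe %*% Conj(t(Xe))) / n_ep
    S[, , b] <- (Sb + Conj(t(Sb))) / 2
  }
  structure(
    list(S = S, freqs = freqs, n_epochs = n_ep, labels = labels),
    class = "cross_spectrum"
  )
}

#' @export
print.cross_spectrum <- function(x, ...) {
  cat(sprintf("<cross_spectrum> %d x %d signals at %d bins, %d epochs\n",
              dim(x$S)[1], dim(x$S)[2], dim(x$S)[3], x$n_epochs))
  invisible(x)
}

#' Lagged coherence between two signals
#'
#' The coherence remaining after the zero-lag (instantaneous) component is
#' removed:
#' \deqn{LagC(f) = Im(S_{ij})^2 / (S_{ii} S_{jj} - Re(S_{ij})^2)}
#' It is 0 exactly when the cross-spectrum is real (purely instantaneous
#' coupling, e.g. volume-conducted mixtures of one source), 0 for
#' independent signals, bounded in \[0,1\], and symmetric in (i, j). A
#' degenerate denominator (perfect instantaneous coherence) is defined as 0
#' with a warning.
#'
#' @param cs a `cross_spectrum`.
#' @param i,j signal indices or labels.
#' @param f optional frequency (Hz) or vector of frequencies; default all
#'   bins.
#' @return Numeric vector of lagged-coherence values in \[0,1\], one per
#'   requested bin.
#' @export
lagged_coherence <- function(cs, i, j, f = NULL) {
  stopifnot(inherits(cs, "cross_spectrum"))
  if (is.character(i)) i <- match(i, cs$labels)
  if (is.character(j)) j <- match(j, cs$labels)
  bins <- if (is.null(f)) seq_along(cs$freqs) else match(f, cs$freqs)
  if (anyNA(bins)) abort("requested frequency not on the analysis grid")
  Sij <- cs$S[i, j, bins]
  Sii <- Re(cs$S[i, i, bins]); Sjj <- Re(cs$S[j, j, bins])
  lagged_coherence_terms(Sij, Sii, Sjj)
}

# Core formula on raw cross-spectral terms (vectorized over bins).
lagged_coherence_terms <- function(Sij, Sii, Sjj) {
  den <- Sii * Sjj - Re(Sij)^2
  num <- Im(Sij)^2
  out <- numeric(length(den))
  bad <- den <= 0
  if (any(bad & num > 1e-14 * pmax(Sii * Sjj, .Machine$double.eps))) {
    warn("degenerate denominator in lagged coherence (perfect instantaneous coherence); defined as 0")
  }
  ok <- !bad
  out[ok] <- pmin(1, pmax(0, num[ok] / den[ok]))
  out
}

#' The canonical ROI pair lists
#'
#' Six homologous inter-hemispherical pairs (left vs right of the same ROI)
#' and fifteen intra-hemispherical pairs (all unordered ROI pairs) per
#' hemisphere.
#'
#' @return Tibble `pair_type` (`inter`, `intra_left`, `intra_right`),
#'   `roi_a`, `roi_b` — 36 rows.
#' @export
roi_pairs <- function() {
  rois <- roi_names()
  inter <- tibble::tibble(pair_type = "inter", roi_a = rois, roi_b = rois)
  cmb <- utils::combn(rois, 2)
  intra <- tibble::tibble(roi_a = cmb[1, ], roi_b = cmb[2, ])
  dplyr::bind_rows(
    inter,
    dplyr::mutate(intra, pair_type = "intra_left", .before = 1),
    dplyr::mutate(intra, pair_type = "intra_right", .before = 1)
  )
}

#' ROI-pair lagged linear connectivity table
#'
#' For each ROI pair and band, the mean over all voxel pairs (one voxel
#' from each ROI side) and over the band's frequency bins (inclusive
#' boundary rule, bins innermost) of the lagged coherence between the
#' voxels' scalar source series. Inter-hemispherical pairs take one voxel
#' set per hemisphere of the same ROI; intra-hemispherical pairs take two
#' ROIs within one hemisphere. When the number of voxel pairs exceeds
#' `max_voxel_pairs` a seeded uniform subsample is used and recorded.
#'
#' @param srcser a [source_series()] object.
#' @param pairs pair list, default [roi_pairs()].
#' @param scheme band scheme, default [band_scheme()].
#' @param max_voxel_pairs cap on voxel pairs per ROI pair (default 500).
#' @param seed seed for the voxel-pair subsample.
#' @return Tibble `pair_type`, `roi_a`, `roi_b`, `band`, `llc`,
#'   `n_voxel_pairs`, `subsampled`: 36 pairs x 7 bands, `llc` in \[0,1\].
#' @export
roi_pair_llc <- function(srcser, pairs = roi_pairs(), scheme = band_scheme(),
                         max_voxel_pairs = 500, seed = 1) {
  stopifnot(inherits(srcser, "source_series"))
  validate_band_scheme(scheme)
  vox <- srcser$voxels
  coef <- srcser$coef
  n_ep <- srcser$n_epochs
  if (n_ep < 2L) abort("connectivity needs at least 2 accepted epochs")
  all_bins <- sort(unique(unlist(
    purrr::pmap(scheme, function(band, f_lo, f_hi) band_bins(srcser$freqs, f_lo, f_hi))
  )))
  # per-voxel auto-power at the needed bins
  P <- matrix(0, nrow(vox), length(all_bins))
  for (bi in seq_along(all_bins)) {
    Xe <- coef[, all_bins[bi], , drop = FALSE]
    dim(Xe) <- c(nrow(vox), n_ep)
    P[, bi] <- rowMeans(abs(Xe)^2)
  }
  bin_pos <- function(f_lo, f_hi) match(band_bins(srcser$freqs, f_lo, f_hi), all_bins)

  vox_set <- function(roi, hemi) which(vox$roi == roi & vox$hemisphere == hemi)
  sub_coef <- coef[, all_bins, , drop = FALSE]

  res <- vector("list", nrow(pairs))
  for (pr in seq_len(nrow(pairs))) {
    pair_type <- pairs$pair_type[pr]; roi_a <- pairs$roi_a[pr]; roi_b <- pairs$roi_b[pr]
    if (pair_type == "inter") {
      va <- vox_set(roi_a, "left"); vb <- vox_set(roi_b, "right")
    } else {
      hemi <- sub("intra_", "", pair_type)
      va <- vox_set(roi_a, hemi); vb <- vox_set(roi_b, hemi)
    }
    if (length(va) == 0L || length(vb) == 0L) {
      abort(sprintf("no voxels for pair %s %s-%s", pair_type, roi_a, roi_b))
    }
    grid <- expand.grid(a = va, b = vb)
    subsampled <- nrow(grid) > max_voxel_pairs
    if (subsampled) {
      grid <- with_seed(seed, grid[sample(nrow(grid), max_voxel_pairs), , drop = FALSE])
    }
    # per voxel-pair lagged coherence over all needed bins
    lc_bins <- matrix(0, nrow(grid), length(all_bins))
    for (g in seq_len(nrow(grid))) {
      ia <- grid$a[g]; ib <- grid$b[g]
      Xa <- sub_coef[ia, , , drop = FALSE]; dim(Xa) <- c(length(all_bins), n_ep)
      Xb <- sub_coef[ib, , , drop = FALSE]; dim(Xb) <- c(length(all_bins), n_ep)
      Sij <- rowMeans(Xa * Conj(Xb))
      lc_bins[g, ] <- lagged_coherence_terms(Sij, P[ia, ], P[ib, ])
    }
    band_llc <- vapply(seq_len(nrow(scheme)), function(b) {
      mean(lc_bins[, bin_pos(scheme$f_lo[b], scheme$f_hi[b]), drop = FALSE])
    }, 0)
    res[[pr]] <- tibble::tibble(
      pair_type = pair_type, roi_a = roi_a, roi_b = roi_b, band = scheme$band,
      llc = band_llc, n_voxel_pairs = nrow(grid), subsampled = subsampled
    )
  }
  out <- dplyr::bind_rows(res)
  out$band <- factor(out$band, levels = scheme$band)
  out
}

#' Monte-Carlo null level for lagged coherence
#'
#' Distribution quantile of band-averaged lagged coherence between two
#' independent signals, as a function of the number of averaged epochs
#' (the dominant determinant of the estimator's null level). Used to judge
#' whether an observed LLC value exceeds chance.
#'
#' @param n_epochs number of epochs averaged in the cross-spectrum.
#' @param n_bins number of frequency bins averaged in the band (default 1).
#' @param prob quantile (default 0.95).
#' @param n_sim Monte-Carlo draws (default 2000).
#' @param seed RNG seed.
#' @return The null-level quantile (scalar).
#' @export
llc_null_level <- function(n_epochs, n_bins = 1, prob = 0.95, n_sim = 2000, seed = 1) {
  with_seed(seed, {
    sims <- vapply(seq_len(n_sim), function(s) {
      mean(vapply(seq_len(n_bins), function(b) {
        X <- complex(real = rnorm(n_epochs), imaginary = rnorm(n_epochs))
        Y <- complex(real = rnorm(n_epochs), imaginary = rnorm(n_epochs))
        Sxy <- mean(X * Conj(Y))
        lagged_coherence_terms(Sxy, mean(abs(X)^2), mean(abs(Y)^2))
      }, 0))
    }, 0)
    as.numeric(quantile(sims, prob))
  })
}
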