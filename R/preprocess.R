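#' Construct a multi-channel EEG recording
#'
#' A recording is a channels x samples matrix in microvolts together with its
#' sampling rate, channel labels and reference state. This is the entry
#' container for the pipeline; [read_recording()] produces one from disk and
#' [simulate_subject()] embeds one in each synthetic subject.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param labels character vector of unique channel labels (10-20 names for
#'   the standard montage); defaults to rownames of `data`.
#' @param reference one of `"linked-earlobe"`, `"common-average"`, `"other"`.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(data, fs, labels = rownames(data),
                          reference = c("other", "linked-earlobe", "common-average")) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  labels <- as.character(labels)
  if (length(labels) != nrow(data)) abort("length(labels) must equal nrow(data)")
  if (anyDuplicated(labels)) abort("duplicate channel labels")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) abort("fs must be a positive scalar (Hz)")
  if (!all(is.finite(data))) abort("recording data must be finite")
  rownames(data) <- labels
  structure(
    list(data = data, fs = fs, labels = labels, reference = reference),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), reference: %s\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$reference
  ))
  invisible(x)
}

#' The 19 standard 10-20 channel labels
#' @return Character vector of length 19.
#' @export
standard_1020_labels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
    "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Re-reference a recording to the common average
#'
#' Subtracts, at every sample, the instantaneous mean across channels, so
#' each column of the output sums to zero. Idempotent, and invariant to
#' adding a constant offset to all channels.
#'
#' @param rec an [new_recording()] object with at least two channels.
#' @return A re-referenced `eeg_recording` with `reference = "common-average"`.
#' @export
rereference_common_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2L) abort("common-average reference needs at least 2 channels")
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data))
  rec$reference <- "common-average"
  rec
}

#' Segment a recording into consecutive non-overlapping epochs
#'
#' Cuts the recording into consecutive epochs of `epoch_length` seconds
#' (default 2 s, the resolution-setting choice: a 2-s epoch yields a 0.5 Hz
#' spectral grid). A trailing partial epoch is discarded. All epochs start
#' out accepted; [reject_artifacts()] updates the mask.
#'
#' @param rec an `eeg_recording`.
#' @param epoch_length epoch duration in seconds; `fs * epoch_length` must be
#'   a whole number of samples.
#' @return An object of class `eeg_epochs` holding a channels x samples x
#'   epochs array, the sampling rate, the accepted mask and per-epoch
#'   rejection reasons.
#' @export
segment_epochs <- function(rec, epoch_length = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  spe <- rec$fs * epoch_length
  if (abs(spe - round(spe)) > 1e-9) abort("fs * epoch_length must be an integer number of samples")
  spe <- as.integer(round(spe))
  n_total <- ncol(rec$data)
  if (n_total < spe) abort(sprintf("recording (%.2f s) shorter than one epoch (%g s)", n_total / rec$fs, epoch_length))
  n_ep <- n_total %/% spe
  a <- array(rec$data[, seq_len(n_ep * spe), drop = FALSE],
             dim = c(nrow(rec$data), spe, n_ep))
  structure(
    list(
      epochs = a, fs = rec$fs, epoch_length = epoch_length,
      labels = rec$labels, reference = rec$reference,
      accepted = rep(TRUE, n_ep), reasons = rep("", n_ep)
    ),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf(
    "<eeg_epochs> %d epochs of %g s (%d channels @ %g Hz), %d accepted\n",
    n_epochs(x), x$epoch_length, dim(x$epochs)[1], x$fs, sum(x$accepted)
  ))
  invisible(x)
}

n_epochs <- function(es) dim(es$epochs)[3]

#' Flag artifact epochs by amplitude and flatline rules
#'
#' An epoch is rejected when any channel's peak absolute amplitude exceeds
#' `abs_threshold` (high-amplitude ocular/muscular/instrumental transients)
#' or when any channel's peak-to-peak amplitude falls below `flat_threshold`
#' (dead channel / saturated amplifier). Previously rejected epochs stay
#' rejected; the data themselves are never modified. Raising `abs_threshold`
#' never rejects more epochs.
#'
#' @param es an `eeg_epochs` object.
#' @param abs_threshold peak absolute amplitude bound in microvolts (> 0).
#' @param flat_threshold minimum peak-to-peak amplitude in microvolts (> 0).
#' @return The epoch set with updated `accepted` mask and `reasons`.
#' @export
reject_artifacts <- function(es, abs_threshold = 100, flat_threshold = 0.1) {
  stopifnot(inherits(es, "eeg_epochs"))
  if (abs_threshold <= 0 || flat_threshold <= 0) abort("thresholds must be > 0")
  for (k in seq_len(n_epochs(es))) {
    ep <- es$epochs[, , k, drop = FALSE]
    dim(ep) <- dim(es$epochs)[1:2]
    if (max(abs(ep)) > abs_threshold) {
      es$accepted[k] <- FALSE
      es$reasons[k] <- paste(setdiff(c(strsplit(es$reasons[k], ",")[[1]], "amplitude"), ""), collapse = ",")
    } else {
      ptp <- apply(ep, 1L, function(x) max(x) - min(x))
      if (any(ptp < flat_threshold)) {
        es$accepted[k] <- FALSE
        es$reasons[k] <- paste(setdiff(c(strsplit(es$reasons[k], ",")[[1]], "flat"), ""), collapse = ",")
      }
    }
  }
  es
}

# Drop rejected epochs (used by the spectral estimators).
accepted_epochs <- function(es) {
  idx <- which(es$accepted)
  if (length(idx) == 0L) abort("no accepted epochs")
  es$epochs[, , idx, drop = FALSE]
}
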