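# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fx_leadfield <- function() {
  if (is.null(.fixtures$lf)) .fixtures$lf <- make_toy_leadfield(19, 1, seed = 7)
  .fixtures$lf
}

fx_inverse <- function(alpha = 0.05) {
  key <- paste0("op_", alpha)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- compute_inverse(fx_leadfield(), alpha = alpha)
  }
  .fixtures[[key]]
}

# 4 + 4 subjects, 20 s each: enough for structural checks, cheap to build.
fx_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    cfg <- sim_config(n_nold = 4, n_ad = 4, duration = 20, seed = 42,
                      artifact_rate = 0)
    .fixtures$cohort <- simulate_cohort(cfg, fx_leadfield())
  }
  .fixtures$cohort
}

# A sinusoidal test recording.
sine_recording <- function(freq, fs = 256, duration = 60, amp = 1, n_channels = 2) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  x <- amp * sin(2 * pi * freq * t)
  new_recording(matrix(rep(x, n_channels), nrow = n_channels, byrow = TRUE),
                fs, paste0("ch", seq_len(n_channels)))
}

# Build an epoch set directly from a signals x samples x epochs array.
epochs_from_array <- function(a, fs, epoch_length = 2) {
  structure(
    list(epochs = a, fs = fs, epoch_length = epoch_length,
         labels = paste0("s", seq_len(dim(a)[1])), reference = "other",
         accepted = rep(TRUE, dim(a)[3]), reasons = rep("", dim(a)[3])),
    class = "eeg_epochs"
  )
}

# --- Independent oracles ----------------------------------------------------

# Exhaustive tie-adjusted pairwise-comparison probability.
oracle_pairwise_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# Lagged coherence at one frequency by explicit DFT sums on epoch matrices
# (samples x epochs), written against the definition, independent of the
# package's FFT path.
oracle_lagged_coherence <- function(xa, xb, fs, fbin) {
  n <- nrow(xa)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  k <- round(fbin * n / fs)
  e <- exp(-2i * pi * k * (0:(n - 1)) / n)
  Sxy <- 0; Sxx <- 0; Syy <- 0
  for (ep in seq_len(ncol(xa))) {
    Xa <- sum(w * xa[, ep] * e)
    Xb <- sum(w * xb[, ep] * e)
    Sxy <- Sxy + Xa * Conj(Xb)
    Sxx <- Sxx + abs(Xa)^2
    Syy <- Syy + abs(Xb)^2
  }
  m <- ncol(xa)
  Im(Sxy / m)^2 / ((Sxx / m) * (Syy / m) - Re(Sxy / m)^2)
}
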