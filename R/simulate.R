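#' Default per-group source band-power profiles
#'
#' Relative source power per ROI and band for the two groups. The control
#' (Nold) profile has a posterior-dominant alpha 1 rhythm (occipital and
#' parietal alpha 1 boosted); the AD profile multiplies delta and theta
#' power by `ad_slow_factor` and alpha 1/alpha 2 power by `ad_alpha_factor`
#' in every ROI, reproducing the direction of the group contrast (higher
#' slow-wave, lower alpha source activity in AD). Magnitudes are free
#' simulation parameters, not estimates from any clinical sample.
#'
#' @param ad_slow_factor multiplier on AD delta/theta source power (default 2).
#' @param ad_alpha_factor multiplier on AD alpha1/alpha2 source power
#'   (default 0.5).
#' @return Named list with `Nold` and `AD`, each a list mapping ROI name to a
#'   named band-power vector.
#' @export
default_profiles <- function(ad_slow_factor = 2, ad_alpha_factor = 0.5) {
  base <- c(delta = 1, theta = 0.8, alpha1 = 1.5, alpha2 = 0.8,
            beta1 = 0.4, beta2 = 0.25, gamma = 0.15)
  nold <- lapply(setNames(roi_names(), roi_names()), function(r) base)
  nold$occipital["alpha1"] <- 4
  nold$occipital["alpha2"] <- 1.2
  nold$parietal["alpha1"] <- 3
  ad <- lapply(nold, function(p) {
    p[c("delta", "theta")] <- p[c("delta", "theta")] * ad_slow_factor
    p[c("alpha1", "alpha2")] <- p[c("alpha1", "alpha2")] * ad_alpha_factor
    p
  })
  list(Nold = nold, AD = ad)
}

#' Default inter-hemispheric alpha coupling specification
#'
#' One lagged shared component between left and right occipital sources in
#' the alpha 1 band, stronger in controls than in AD (reduced lagged alpha
#' coupling in the patient group). `lag` is in samples and must be >= 1 so
#' the shared component is genuinely lagged, not instantaneous.
#'
#' @return Tibble with columns `roi_a`, `roi_b` (ROI_hemisphere labels),
#'   `band`, `lag`, `strength` (fraction of band power shared, in \[0,1\])
#'   and `group` (`NA` = both groups).
#' @export
default_coupling <- function() {
  tibble::tibble(
    roi_a = "occipital_left", roi_b = "occipital_right",
    band = "alpha1", lag = 3L,
    strength = c(0.6, 0.2), group = c("Nold", "AD")
  )
}

#' Synthetic cohort configuration
#'
#' Bundles every knob of the synthetic EEG cohort generator. Defaults mirror
#' the study design the pipeline targets: 100 controls and 120 patients,
#' about 5 min of eyes-closed EEG per subject at 128 Hz, 2-s epochs, group
#' IAF means 10.0 vs 8.5 Hz.
#'
#' @param n_nold,n_ad group sizes (>= 0).
#' @param fs sampling rate, 128 or 256 Hz.
#' @param duration recording length in seconds (default 300).
#' @param seed master seed; all per-subject seeds derive from it.
#' @param profile per-group band-power profiles, see [default_profiles()].
#' @param iaf_mean_nold,iaf_mean_ad,iaf_sd group IAF distributions (Hz).
#' @param coupling lagged-coupling specification, see [default_coupling()];
#'   `NULL` disables coupling.
#' @param sensor_noise_sd white sensor noise SD in microvolts.
#' @param artifact_rate fraction of 2-s epochs corrupted with 200 uV
#'   half-second transients (exercises the rejection path).
#' @param subject_sd SD of the per-subject log-normal jitter applied to each
#'   (ROI, band) source power; this is the between-subject biological
#'   variability that controls marker effect sizes.
#' @param severity_sd SD of the per-AD-subject disease-severity scalar
#'   (mean 1); severity geometrically interpolates each AD power between the
#'   Nold and AD profile and drives MMSE and brain volumes.
#' @param scalp_rms target root-mean-square scalp amplitude in microvolts
#'   before sensor noise.
#' @param with_volumes generate GM/WM/CSF volumes (ml) per subject.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_nold = 100, n_ad = 120, fs = 128, duration = 300,
                       seed = 1, profile = default_profiles(),
                       iaf_mean_nold = 10, iaf_mean_ad = 8.5, iaf_sd = 0.8,
                       coupling = default_coupling(),
                       sensor_noise_sd = 2, artifact_rate = 0.05,
                       subject_sd = 0.8, severity_sd = 0.3,
                       scalp_rms = 8, with_volumes = TRUE) {
  if (n_nold < 0 || n_ad < 0) abort("group sizes must be >= 0")
  if (!fs %in% c(128, 256)) abort("fs must be 128 or 256 Hz")
  if (artifact_rate < 0 || artifact_rate > 1) abort("artifact_rate must be in [0,1]")
  if (!is.null(coupling) && nrow(coupling) > 0 && any(coupling$lag < 1)) {
    abort("coupling lag must be >= 1 sample (lagged, not instantaneous)")
  }
  for (g in names(profile)) for (r in names(profile[[g]])) {
    if (any(profile[[g]][[r]] < 0)) abort("band powers must be >= 0")
  }
  structure(
    list(n_nold = as.integer(n_nold), n_ad = as.integer(n_ad),
         fs = fs, duration = duration, seed = as.integer(seed),
         profile = profile, iaf_mean_nold = iaf_mean_nold,
         iaf_mean_ad = iaf_mean_ad, iaf_sd = iaf_sd, coupling = coupling,
         sensor_noise_sd = sensor_noise_sd, artifact_rate = artifact_rate,
         subject_sd = subject_sd, severity_sd = severity_sd,
         scalp_rms = scalp_rms, with_volumes = with_volumes),
    class = "sim_config"
  )
}

# Oscillator centre frequencies / bandwidths per band; alpha1 is centred on
# the subject's drawn IAF.
band_oscillator_params <- function(iaf) {
  tibble::tibble(
    band = band_names(),
    f0 = c(3, 6, iaf, 11.75, 16.5, 25, 35),
    bw = c(1.5, 2.5, 1.2, 1.5, 4, 6, 6)
  )
}

# Unit-variance resonant AR(2) band oscillator: poles at radius
# exp(-pi*bw/fs) and angle 2*pi*f0/fs, driven by white noise.
ar2_band <- function(n, fs, f0, bw) {
  r <- exp(-pi * bw / fs)
  phi <- c(2 * r * cos(2 * pi * f0 / fs), -r^2)
  x <- as.numeric(stats::filter(rnorm(n), phi, method = "recursive"))
  x / sd(x)
}

parse_roi_hemi <- function(label) {
  parts <- strsplit(label, "_", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% roi_names() ||
      !parts[2] %in% c("left", "right")) {
    abort(sprintf("coupling label '%s' must be '<roi>_<left|right>'", label))
  }
  list(roi = parts[1], hemi = parts[2])
}

#' Simulate one subject's recording and metadata
#'
#' Each voxel's source signal is a sum of band-limited stochastic
#' oscillators (resonant second-order autoregressive processes) with powers
#' taken from the group profile, multiplied by a per-subject log-normal
#' jitter shared across the voxels of an (ROI, band) cell. The subject's
#' alpha 1 oscillator is centred on an IAF drawn from the group
#' distribution. Coupled ROI pairs share a common band component injected
#' with the specified sample lag. Scalp data are `gain x sources` (fixed
#' per-voxel orientations) rescaled to the target RMS, plus white sensor
#' noise; a fraction `artifact_rate` of 2-s segments receives a
#' high-amplitude transient. Deterministic given `subject_seed`.
#'
#' @param config a [sim_config()].
#' @param leadfield an [make_toy_leadfield()] leadfield covering every ROI
#'   named in the profiles and couplings.
#' @param group `"Nold"` or `"AD"`.
#' @param subject_seed integer seed for this subject.
#' @param id subject identifier.
#' @return A list of class `subject_record`: id, group, age, education,
#'   gender, mmse, optional gm/wm/csf volumes, drawn IAF, severity, and the
#'   `eeg_recording`.
#' @export
simulate_subject <- function(config, leadfield, group = c("Nold", "AD"),
                             subject_seed = 1, id = "sub001") {
  group <- match.arg(group)
  validate_leadfield(leadfield)
  vox <- leadfield$voxels
  prof <- config$profile
  missing_roi <- setdiff(names(prof[[group]]), unique(vox$roi))
  if (length(missing_roi)) {
    abort(paste("leadfield lacks ROIs named in profile:", paste(missing_roi, collapse = ", ")))
  }
  cpl <- config$coupling
  if (!is.null(cpl) && nrow(cpl) > 0) {
    for (lab in c(cpl$roi_a, cpl$roi_b)) {
      ph <- parse_roi_hemi(lab)
      if (!any(vox$roi == ph$roi & vox$hemisphere == ph$hemi)) {
        abort(sprintf("coupling references '%s' absent from the leadfield", lab))
      }
    }
    cpl <- cpl[is.na(cpl$group) | cpl$group == group, , drop = FALSE]
  }

  fs <- config$fs
  n_samp <- round(fs * config$duration)
  pad <- 4L * fs
  n_tot <- n_samp + pad

  with_seed(subject_seed, {
    severity <- if (group == "AD") max(0.2, rnorm(1, 1, config$severity_sd)) else 0
    iaf_mean <- if (group == "AD") config$iaf_mean_ad else config$iaf_mean_nold
    iaf <- min(13, max(7.5, rnorm(1, iaf_mean, config$iaf_sd)))
    osc <- band_oscillator_params(iaf)

    rois <- names(prof$Nold)
    jitter <- matrix(exp(rnorm(length(rois) * 7, 0, config$subject_sd)),
                     nrow = length(rois), dimnames = list(rois, band_names()))

    # effective power: geometric interpolation Nold -> AD by severity
    power_of <- function(roi, band) {
      p0 <- prof$Nold[[roi]][band]
      p1 <- (prof[[group]] %||% prof$Nold)[[roi]][band]
      p <- if (group == "AD") p0 * (p1 / p0)^severity else p0
      unname(p * jitter[roi, band])
    }

    # pre-draw shared components for couplings
    shared <- list()
    if (!is.null(cpl) && nrow(cpl) > 0) {
      for (k in seq_len(nrow(cpl))) {
        shared[[k]] <- ar2_band(n_tot + cpl$lag[k],
                                fs, osc$f0[osc$band == cpl$band[k]],
                                osc$bw[osc$band == cpl$band[k]])
      }
    }

    S <- matrix(0, nrow(vox), n_samp)
    for (v in seq_len(nrow(vox))) {
      sv <- numeric(n_tot)
      for (b in seq_len(nrow(osc))) {
        band <- osc$band[b]
        p <- power_of(vox$roi[v], band)
        if (p <= 0) next
        comp <- ar2_band(n_tot, fs, osc$f0[b], osc$bw[b])
        # mix in lagged shared components where this voxel participates
        if (!is.null(cpl) && nrow(cpl) > 0) {
          for (k in seq_len(nrow(cpl))) {
            if (cpl$band[k] != band) next
            pa <- parse_roi_hemi(cpl$roi_a[k]); pb <- parse_roi_hemi(cpl$roi_b[k])
            s <- cpl$strength[k]; lag <- cpl$lag[k]
            if (vox$roi[v] == pa$roi && vox$hemisphere[v] == pa$hemi) {
              comp <- sqrt(1 - s) * comp + sqrt(s) * shared[[k]][(1 + lag):(n_tot + lag)]
            } else if (vox$roi[v] == pb$roi && vox$hemisphere[v] == pb$hemi) {
              comp <- sqrt(1 - s) * comp + sqrt(s) * shared[[k]][1:n_tot]
            }
          }
        }
        sv <- sv + sqrt(p) * comp
      }
      S[v, ] <- sv[(pad + 1L):n_tot]
    }

    X <- effective_gain(leadfield) %*% S
    X <- X * (config$scalp_rms / sqrt(mean(X^2)))
    X <- X + matrix(rnorm(length(X), 0, config$sensor_noise_sd), nrow(X))

    # epoch-aligned high-amplitude transients
    n_ep <- floor(config$duration / 2)
    n_art <- round(config$artifact_rate * n_ep)
    if (n_art > 0) {
      bad <- sample(n_ep, n_art)
      for (ep in bad) {
        ch <- sample(nrow(X), 1L)
        onset <- (ep - 1L) * 2L * fs + sample(fs, 1L)
        idx <- onset:min(onset + fs %/% 2 - 1L, ncol(X))
        X[ch, idx] <- X[ch, idx] + 200
      }
    }

    age <- rnorm(1, 70, 6)
    education <- max(0, rnorm(1, 10, 4))
    gender <- sample(c("F", "M"), 1L)
    mmse_mu <- 28.5 - 7 * severity
    mmse <- min(30, max(0, round(rnorm(1, mmse_mu, 1.2))))
    vols <- list(gm_vol = NA_real_, wm_vol = NA_real_, csf_vol = NA_real_)
    if (isTRUE(config$with_volumes)) {
      total <- 1450
      gm_f <- max(0.25, 0.42 - 0.03 * severity + rnorm(1, 0, 0.012))
      csf_f <- max(0.1, 0.23 + 0.035 * severity + rnorm(1, 0, 0.012))
      wm_f <- max(0.1, 1 - gm_f - csf_f)
      vols <- list(gm_vol = gm_f * total, wm_vol = wm_f * total, csf_vol = csf_f * total)
    }

    structure(
      c(list(id = id, group = group, age = age, education = education,
             gender = gender, mmse = mmse, iaf_true = iaf, severity = severity),
        vols,
        list(recording = new_recording(X, fs, leadfield$channels, reference = "other"))),
      class = "subject_record"
    )
  })
}

#' Simulate a full two-group cohort
#'
#' Generates `n_nold + n_ad` subjects with per-subject seeds derived
#' deterministically from `config$seed`. Identical (config, leadfield)
#' inputs reproduce the cohort bit-for-bit. By construction the AD group's
#' MMSE mean is below the Nold mean (severity-driven), while age and
#' education distributions are matched between groups.
#'
#' @param config a [sim_config()].
#' @param leadfield an `eeg_leadfield`.
#' @return A list of `subject_record`s of class `eeg_cohort`.
#' @export
simulate_cohort <- function(config, leadfield) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_nold + config$n_ad
  groups <- rep(c("Nold", "AD"), c(config$n_nold, config$n_ad))
  records <- vector("list", n)
  for (i in seq_len(n)) {
    records[[i]] <- simulate_subject(
      config, leadfield, groups[i],
      subject_seed = derive_seed(config$seed, i),
      id = sprintf("sub%03d", i)
    )
  }
  structure(records, class = "eeg_cohort", config = config)
}

#' @export
print.eeg_cohort <- function(x, ...) {
  g <- table(vapply(x, `[[`, "", "group"))
  cat(sprintf("<eeg_cohort> %d subjects (%s)\n", length(x),
              paste(names(g), g, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Cohort manifest table
#'
#' @param cohort an `eeg_cohort`.
#' @return Tibble with one row per subject: id, group, demographics, MMSE,
#'   volumes, drawn IAF and severity.
#' @export
cohort_manifest <- function(cohort) {
  purrr::map_dfr(cohort, function(s) {
    tibble::tibble(
      subject = s$id, group = s$group, age = s$age, education = s$education,
      gender = s$gender, mmse = s$mmse, gm_vol = s$gm_vol, wm_vol = s$wm_vol,
      csf_vol = s$csf_vol, iaf_true = s$iaf_true, severity = s$severity
    )
  })
}
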