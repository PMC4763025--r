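#' Process one subject end to end
#'
#' Runs the per-subject chain: common-average re-reference, 2-s
#' segmentation, artifact rejection, Welch spectra and IAF at the channel
#' level, source projection with grand-mean normalization and ROI
#' aggregation, and (optionally) ROI-pair lagged linear connectivity.
#'
#' @param record a `subject_record` (or any list with `id` and a
#'   `recording`).
#' @param op an `eeg_inverse` computed from the cohort's leadfield.
#' @param abs_threshold,flat_threshold artifact thresholds, see
#'   [reject_artifacts()].
#' @param scheme band scheme.
#' @param connectivity compute the LLC table (default TRUE).
#' @param max_voxel_pairs,llc_seed see [roi_pair_llc()].
#' @return List: `activity` (tibble subject, roi, band, value), `llc`
#'   (tibble or NULL), `iaf` (Hz), `n_accepted` epochs.
#' @export
process_subject <- function(record, op, abs_threshold = 100, flat_threshold = 0.1,
                            scheme = band_scheme(), connectivity = TRUE,
                            max_voxel_pairs = 500, llc_seed = 1) {
  rec <- rereference_common_average(record$recording)
  es <- reject_artifacts(segment_epochs(rec, 2), abs_threshold, flat_threshold)
  sp <- welch_psd(es)
  iaf <- detect_iaf(sp)
  ss <- normalize_current_density(apply_inverse(op, es))
  act <- aggregate_roi(ss, scheme)
  act <- dplyr::mutate(act, subject = record$id, .before = 1)
  llc <- NULL
  if (connectivity) {
    srcser <- source_series(op, es)
    llc <- roi_pair_llc(srcser, scheme = scheme,
                        max_voxel_pairs = max_voxel_pairs, seed = llc_seed)
    llc <- dplyr::mutate(llc, subject = record$id, .before = 1)
  }
  list(activity = act, llc = llc, iaf = iaf, n_accepted = sum(es$accepted))
}

#' Analyze a cohort: markers, screening, ROC, stratification
#'
#' The in-memory orchestration of the whole marker analysis on a cohort of
#' subject records: per-subject processing ([process_subject()]), marker
#' construction from the registry, the covariate-adjusted t-screen, ROC
#' evaluation of the screened markers, and AD+/AD- stratification on the
#' best marker with MMSE and normalized-volume subgroup comparisons.
#'
#' @param cohort an `eeg_cohort` (simulated or read from disk).
#' @param leadfield the `eeg_leadfield` the cohort was generated/recorded
#'   under.
#' @param inverse optional precomputed `eeg_inverse` (saves recomputation
#'   across cohorts sharing a leadfield).
#' @param registry marker registry, default [default_marker_registry()].
#' @param alpha_screen screening level.
#' @param auroc_threshold "moderate" classification floor (strict `>`).
#' @param covariates covariate columns for the screen (e.g. `age`,
#'   `education`, `gender`, `iaf`). Default `NULL`: the gate into ROC
#'   analysis is a plain independent t-test per composite marker. Note that
#'   pooled residualization on a covariate that itself differs between
#'   groups (IAF slowing is part of the disease) also removes group signal
#'   carried by that covariate.
#' @param connectivity compute LLC markers (default TRUE).
#' @param stratify_marker marker for stratification; default the
#'   best-AUROC marker.
#' @param abs_threshold,flat_threshold,max_voxel_pairs,alpha,tol,max_iter
#'   stage parameters passed through.
#' @return List of class `eeg_study`: `meta`, `activity`, `llc`, `markers`,
#'   `screen`, `roc`, `strat`, `comparisons`, `inverse`.
#' @export
analyze_cohort <- function(cohort, leadfield, inverse = NULL,
                           registry = default_marker_registry(),
                           alpha_screen = 0.05, auroc_threshold = 0.70,
                           covariates = NULL,
                           connectivity = TRUE, stratify_marker = NULL,
                           abs_threshold = 100, flat_threshold = 0.1,
                           max_voxel_pairs = 500,
                           alpha = 0.05, tol = 1e-6, max_iter = 100) {
  op <- inverse %||% compute_inverse(leadfield, alpha = alpha, tol = tol, max_iter = max_iter)
  per <- purrr::map(cohort, process_subject, op = op,
                    abs_threshold = abs_threshold, flat_threshold = flat_threshold,
                    connectivity = connectivity, max_voxel_pairs = max_voxel_pairs)
  activity <- purrr::map_dfr(per, "activity")
  llc <- if (connectivity) purrr::map_dfr(per, "llc") else NULL
  meta <- cohort_manifest(cohort)
  meta$iaf <- vapply(per, `[[`, 0, "iaf")
  meta$n_accepted_epochs <- vapply(per, `[[`, 0, "n_accepted")

  markers <- build_markers(activity, llc, registry)
  screen <- screen_markers(markers, meta, alpha = alpha_screen, covariates = covariates)
  roc <- evaluate_markers(markers, screen, meta, auroc_threshold = auroc_threshold)

  strat <- NULL
  comparisons <- NULL
  if (nrow(roc) > 0 && min(table(meta$group)) >= 2) {
    mk <- stratify_marker %||% attr(roc, "best")
    strat <- stratify_ad(markers, meta, mk)
    comp <- list(mmse = compare_subgroups(
      strat, tibble::tibble(subject = meta$subject, value = meta$mmse), tail = "less"))
    if (all(c("gm_vol", "wm_vol", "csf_vol") %in% names(meta)) &&
        any(is.finite(meta$gm_vol))) {
      vols <- normalize_volumes(tibble::tibble(
        subject = meta$subject, gm = meta$gm_vol, wm = meta$wm_vol, csf = meta$csf_vol
      ))
      comp$gm <- compare_subgroups(strat, tibble::tibble(subject = vols$subject, value = vols$gm_norm), "less")
      comp$wm <- compare_subgroups(strat, tibble::tibble(subject = vols$subject, value = vols$wm_norm), "less")
      comp$csf <- compare_subgroups(strat, tibble::tibble(subject = vols$subject, value = vols$csf_norm), "greater")
    }
    comparisons <- dplyr::bind_rows(comp, .id = "outcome")
  }
  structure(
    list(meta = meta, activity = activity, llc = llc, markers = markers,
         screen = screen, roc = roc, strat = strat, comparisons = comparisons,
         inverse = op),
    class = "eeg_study"
  )
}

#' @export
print.eeg_study <- function(x, ...) {
  cat(sprintf("<eeg_study> %d subjects, %d markers, %d screened, %d above AUROC threshold\n",
              nrow(x$meta), length(unique(x$markers$marker)),
              sum(x$screen$selected), sum(x$roc$selected)))
  if (nrow(x$roc) > 0) {
    b <- x$roc[1, ]
    cat(sprintf("  best: %s (AUROC %.3f, sens %.1f%%, spec %.1f%%, acc %.1f%%)\n",
                b$marker, b$auroc, 100 * b$sensitivity, 100 * b$specificity,
                100 * b$accuracy))
  }
  invisible(x)
}

#' Configuration for the controlled-separation simulation study
#'
#' Builds a [sim_config()] in which only the occipital delta and alpha 1
#' source powers differ between groups (delta multiplied by `delta_factor`,
#' alpha 1 by `alpha_factor` in the patient group), and the per-subject
#' power jitter is calibrated analytically so the occipital delta/alpha 1
#' marker attains a prescribed standardized group separation `d` at the end
#' of the pipeline. Under this (log-)normal marker model, the expected
#' AUROC is `pnorm(d / sqrt(2))`.
#'
#' The calibration accounts for inverse-solution crosstalk: the estimated
#' occipital value mixes contributions from every ROI's sources, which
#' dilutes both the programmed group offset and the between-subject
#' variance. Both effects are computed from the inverse operator (lognormal
#' moments with a delta-method variance), and the jitter SD solved by root
#' finding — no simulation involved.
#'
#' @param leadfield the leadfield of the study.
#' @param inverse optional precomputed `eeg_inverse` for the same leadfield.
#' @param d target standardized separation of log occipital delta/alpha 1
#'   (default 1.2).
#' @param n_per_group subjects per group (default 60).
#' @param seed master seed.
#' @param fs,duration recording parameters (defaults 128 Hz, 60 s).
#' @param delta_factor,alpha_factor AD occipital multipliers (2 and 0.5).
#' @return A `sim_config`.
#' @export
separation_study_config <- function(leadfield, inverse = NULL, d = 1.2,
                                    n_per_group = 60, seed = 1,
                                    fs = 128, duration = 60,
                                    delta_factor = 2, alpha_factor = 0.5) {
  prof_n <- default_profiles()$Nold
  prof_a <- prof_n
  prof_a$occipital["delta"] <- prof_a$occipital["delta"] * delta_factor
  prof_a$occipital["alpha1"] <- prof_a$occipital["alpha1"] * alpha_factor
  op <- inverse %||% compute_inverse(leadfield)
  sd_j <- calibrate_subject_sd(leadfield, op, prof_n, delta_factor, alpha_factor, d)
  sim_config(
    n_nold = n_per_group, n_ad = n_per_group, fs = fs, duration = duration,
    seed = seed, profile = list(Nold = prof_n, AD = prof_a),
    iaf_mean_nold = 10, iaf_mean_ad = 10, iaf_sd = 0.3,
    coupling = NULL, sensor_noise_sd = 1, artifact_rate = 0,
    subject_sd = sd_j, severity_sd = 0, with_volumes = TRUE
  )
}

# Solve for the per-(ROI, band) log-normal jitter SD that delivers a target
# standardized separation of the occipital log delta/alpha1 marker, given
# the crosstalk of the inverse operator.
calibrate_subject_sd <- function(leadfield, op, profile_nold,
                                 delta_factor, alpha_factor, target_d) {
  G <- effective_gain(leadfield)
  nv <- n_voxels(leadfield)
  # crosstalk: power at estimated voxel v from a unit-power source at voxel w
  A <- matrix(0, nv, nv)
  for (w in seq_len(nv)) {
    J <- op$M %*% G[, w]
    A[, w] <- rowsum(as.numeric(J)^2, rep(seq_len(nv), each = 3L)) / 3
  }
  occ <- which(leadfield$voxels$roi == "occipital")
  rois <- roi_names()
  # contribution of each source ROI to the estimated occipital value
  contrib <- function(band, group) {
    vapply(rois, function(r) {
      w <- which(leadfield$voxels$roi == r)
      p <- profile_nold[[r]][band]
      mult <- 1
      if (group == "AD" && r == "occipital") {
        mult <- if (band == "delta") delta_factor else if (band == "alpha1") alpha_factor else 1
      }
      sum(A[occ, w, drop = FALSE]) * p * mult
    }, 0)
  }
  ks <- list(
    d_N = contrib("delta", "Nold"), d_A = contrib("delta", "AD"),
    a_N = contrib("alpha1", "Nold"), a_A = contrib("alpha1", "AD")
  )
  moments <- function(k, s2) {
    vlog <- (exp(s2) - 1) * sum(k^2) / sum(k)^2
    list(mu = log(sum(k)) + s2 / 2 - vlog / 2, v = vlog)
  }
  d_of <- function(sigma) {
    s2 <- sigma^2
    m <- lapply(ks, moments, s2 = s2)
    delta <- (m$d_A$mu - m$a_A$mu) - (m$d_N$mu - m$a_N$mu)
    pooled <- mean(c(m$d_N$v + m$a_N$v, m$d_A$v + m$a_A$v))
    delta / sqrt(pooled)
  }
  stats::uniroot(function(s) d_of(s) - target_d, c(0.02, 5), tol = 1e-6)$root
}
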