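#' Default marker registry
#'
#' The candidate EEG markers evaluated by the pipeline: 12 composite
#' (ratio) current-density markers — delta/alpha1 in all six ROIs,
#' theta/alpha1 in the frontal ROI, delta/alpha2 in central, parietal,
#' occipital, temporal and limbic — and 6 composite connectivity markers
#' (delta/alpha1 inter-hemispherical occipital; delta/alpha1 left
#' intra-hemispherical parietal-occipital and occipital-temporal;
#' theta/alpha1 left and right intra-hemispherical occipital-temporal;
#' theta/alpha2 right intra-hemispherical occipital-temporal). With
#' `include_simple = TRUE` the simple (non-ratio) alpha 1 right
#' intra-hemispherical parietal-limbic connectivity marker is added as a
#' further candidate.
#'
#' Every ratio composite puts the slow band in the numerator, so the
#' AD-abnormal direction is "greater" (higher slow/alpha ratio in
#' patients); the simple alpha connectivity marker is abnormal-low
#' (`direction = "less"`).
#'
#' @param include_simple add the simple alpha1 connectivity candidate.
#' @return Tibble: `marker`, `source` (`activity`/`llc`), `roi_a`, `roi_b`,
#'   `pair_type`, `num_band`, `den_band` (`NA` for simple markers),
#'   `direction`.
#' @export
default_marker_registry <- function(include_simple = FALSE) {
  act <- tibble::tibble(
    source = "activity",
    roi_a = c(roi_names(), "frontal", "central", "parietal", "occipital", "temporal", "limbic"),
    roi_b = NA_character_, pair_type = NA_character_,
    num_band = c(rep("delta", 6), "theta", rep("delta", 5)),
    den_band = c(rep("alpha1", 7), rep("alpha2", 5)),
    direction = "greater"
  )
  llc <- tibble::tibble(
    source = "llc",
    roi_a = c("occipital", "parietal", "occipital", "occipital", "occipital", "occipital"),
    roi_b = c("occipital", "occipital", "temporal", "temporal", "temporal", "temporal"),
    pair_type = c("inter", "intra_left", "intra_left", "intra_left", "intra_right", "intra_right"),
    num_band = c("delta", "delta", "delta", "theta", "theta", "theta"),
    den_band = c("alpha1", "alpha1", "alpha1", "alpha1", "alpha1", "alpha2"),
    direction = "greater"
  )
  reg <- dplyr::bind_rows(act, llc)
  if (include_simple) {
    reg <- dplyr::bind_rows(reg, tibble::tibble(
      source = "llc", roi_a = "parietal", roi_b = "limbic",
      pair_type = "intra_right", num_band = "alpha1", den_band = NA_character_,
      direction = "less"
    ))
  }
  dplyr::mutate(reg, marker = marker_name(reg), .before = 1)
}

marker_name <- function(reg) {
  vapply(seq_len(nrow(reg)), function(i) {
    loc <- if (reg$source[i] == "activity") reg$roi_a[i]
           else if (reg$pair_type[i] == "inter") paste0(reg$roi_a[i], "_", reg$pair_type[i])
           else paste0(reg$roi_a[i], "_", reg$roi_b[i], "_", reg$pair_type[i])
    bands <- if (is.na(reg$den_band[i])) reg$num_band[i]
             else paste0(reg$num_band[i], "_", reg$den_band[i])
    suffix <- if (reg$source[i] == "llc") "_llc" else ""
    paste0(loc, "_", bands, suffix)
  }, "")
}

#' Build simple and composite (ratio) markers
#'
#' Assembles per-subject marker values from the ROI x band current-density
#' table and, optionally, the ROI-pair connectivity table, according to a
#' marker registry. Ratio markers divide the numerator-band by the
#' denominator-band value at the same ROI (or ROI pair); simple markers
#' copy values. Because both bands share the same grand-mean normalization
#' constant, ratio current-density markers are invariant to it.
#'
#' @param activity tibble `subject`, `roi`, `band`, `value` (per-subject
#'   ROI x band normalized current density).
#' @param llc optional tibble `subject`, `pair_type`, `roi_a`, `roi_b`,
#'   `band`, `llc` (or `value`).
#' @param registry a marker registry, default [default_marker_registry()].
#' @return Long tibble `subject`, `marker`, `value`, with the registry
#'   attached as attribute `"registry"`.
#' @export
build_markers <- function(activity, llc = NULL, registry = default_marker_registry()) {
  stopifnot(is.data.frame(activity))
  activity <- dplyr::mutate(activity, roi = as.character(.data$roi), band = as.character(.data$band))
  if (!is.null(llc)) {
    if (!"value" %in% names(llc) && "llc" %in% names(llc)) llc <- dplyr::rename(llc, value = "llc")
    llc <- dplyr::mutate(llc, band = as.character(.data$band))
  }
  get_values <- function(row, band) {
    if (row$source == "activity") {
      v <- dplyr::filter(activity, .data$roi == row$roi_a, .data$band == !!band)
      if (nrow(v) == 0L) abort(sprintf("marker %s: no activity values for %s %s", row$marker, row$roi_a, band))
    } else {
      if (is.null(llc)) abort(sprintf("marker %s needs a connectivity table", row$marker))
      v <- dplyr::filter(llc, .data$pair_type == row$pair_type,
                         .data$roi_a == row$roi_a, .data$roi_b == row$roi_b,
                         .data$band == !!band)
      if (nrow(v) == 0L) {
        abort(sprintf("marker %s: no connectivity values for %s %s-%s %s",
                      row$marker, row$pair_type, row$roi_a, row$roi_b, band))
      }
    }
    v[, c("subject", "value")]
  }
  out <- purrr::map_dfr(seq_len(nrow(registry)), function(i) {
    row <- registry[i, ]
    num <- get_values(row, row$num_band)
    if (is.na(row$den_band)) {
      val <- num
    } else {
      den <- get_values(row, row$den_band)
      val <- dplyr::inner_join(num, den, by = "subject", suffix = c("_num", "_den"))
      zero <- val$subject[val$value_den == 0]
      if (length(zero)) {
        abort(sprintf("marker %s: zero denominator for subject(s) %s",
                      row$marker, paste(zero, collapse = ", ")))
      }
      val <- tibble::tibble(subject = val$subject, value = val$value_num / val$value_den)
    }
    tibble::tibble(subject = val$subject, marker = row$marker, value = val$value)
  })
  attr(out, "registry") <- registry
  out
}

#' Screen markers for group differences before ROC analysis
#'
#' Gates marker candidates into the ROC stage with a covariate-adjusted
#' one-tailed two-sample (Welch) t-test per marker, without multiple-testing
#' correction — the screen is deliberately liberal, since its role is to
#' reduce the candidate set, not to establish group differences. When
#' covariates are supplied, each marker is first residualized on them by
#' ordinary least squares over the pooled sample (group-blind, so
#' group-mean differences attributable to group are preserved).
#'
#' The one-tailed direction defaults to each marker's registered
#' AD-abnormal direction (`direction = "registry"`), which keeps the null
#' selection rate at `alpha`. `"auto"` instead takes the tail from the
#' observed difference (null selection rate `2 * alpha`); `"greater"` /
#' `"less"` force one tail for all markers.
#'
#' @param markers long marker table from [build_markers()].
#' @param meta tibble with `subject`, `group` (`Nold`/`AD`) and any
#'   covariate columns.
#' @param alpha screening level (default 0.05).
#' @param covariates character vector of `meta` column names to residualize
#'   on (e.g. `c("age", "education", "iaf", "gender")`), or `NULL`.
#' @param direction `"registry"`, `"auto"`, `"greater"` or `"less"`.
#' @return Tibble of class `eeg_screen`: `marker`, `mean_nold`, `mean_ad`,
#'   `t`, `df`, `p`, `direction`, `selected`.
#' @export
screen_markers <- function(markers, meta, alpha = 0.05, covariates = NULL,
                           direction = c("registry", "auto", "greater", "less")) {
  direction <- match.arg(direction)
  registry <- attr(markers, "registry")
  if (direction == "registry" && is.null(registry)) direction <- "auto"
  meta <- dplyr::distinct(meta[, unique(c("subject", "group", covariates))])
  if (min(table(meta$group)) < 2 || length(unique(meta$group)) != 2) {
    abort("screening needs two groups with at least 2 subjects each")
  }
  # a covariate with a single observed level carries no information and
  # would break the OLS residualization
  covariates <- covariates[vapply(covariates, function(cv) length(unique(meta[[cv]])) > 1, TRUE)]
  if (length(covariates) == 0L) covariates <- NULL
  out <- purrr::map_dfr(unique(markers$marker), function(mk) {
    d <- dplyr::inner_join(markers[markers$marker == mk, ], meta, by = "subject")
    x <- d$value
    if (!is.null(covariates) && length(covariates)) {
      fml <- stats::reformulate(covariates, response = "value")
      x <- resid(lm(fml, data = d))
    }
    ad <- x[d$group == "AD"]; nold <- x[d$group == "Nold"]
    dir_mk <- switch(direction,
      registry = registry$direction[match(mk, registry$marker)],
      auto = if (mean(ad) >= mean(nold)) "greater" else "less",
      direction
    )
    if (sd(c(ad, nold)) == 0) {
      warn(sprintf("marker %s is constant; p set to 1", mk))
      return(tibble::tibble(marker = mk,
                            mean_nold = mean(d$value[d$group == "Nold"]),
                            mean_ad = mean(d$value[d$group == "AD"]),
                            t = 0, df = NA_real_, p = 1,
                            direction = dir_mk, selected = FALSE))
    }
    tt <- t.test(ad, nold, alternative = dir_mk)
    tibble::tibble(marker = mk,
                   mean_nold = mean(d$value[d$group == "Nold"]),
                   mean_ad = mean(d$value[d$group == "AD"]),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value, direction = dir_mk,
                   selected = tt$p.value < alpha)
  })
  attr(out, "alpha") <- alpha
  class(out) <- c("eeg_screen", class(out))
  out
}
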