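#' Stratify AD subjects against the control reference (AD+/AD-)
#'
#' An AD subject is marker-"positive" (AD+) when the marker value is equal
#' to or higher than the mean plus one sample (n-1) standard deviation of
#' the marker in the Nold reference population, and AD- otherwise. Markers
#' whose AD-abnormal direction is low are sign-flipped first (recorded), so
#' "positive" always means abnormal. The threshold is equivariant under a
#' common shift of all marker values.
#'
#' @param markers long marker table from [build_markers()].
#' @param meta tibble with `subject` and `group`.
#' @param marker marker name to stratify on.
#' @param flip sign-flip the marker before applying the rule (for
#'   abnormal-low markers); `NULL` takes the flip from the registry
#'   direction if available, else `FALSE`.
#' @return Object of class `eeg_strat`: reference mean/SD, threshold
#'   (mean + 1 SD), per-AD-subject status tibble, subgroup sizes.
#' @export
stratify_ad <- function(markers, meta, marker, flip = NULL) {
  d <- dplyr::inner_join(markers[markers$marker == marker, ],
                         dplyr::distinct(meta[, c("subject", "group")]),
                         by = "subject")
  if (nrow(d) == 0L) abort(sprintf("marker '%s' not found", marker))
  if (is.null(flip)) {
    registry <- attr(markers, "registry")
    flip <- !is.null(registry) &&
      identical(registry$direction[match(marker, registry$marker)], "less")
  }
  v <- if (flip) -d$value else d$value
  nold <- v[d$group == "Nold"]
  if (length(nold) < 2L) abort("need at least 2 Nold subjects for the reference")
  m <- mean(nold); s <- sd(nold)
  if (s == 0) abort("degenerate reference: zero Nold standard deviation")
  threshold <- m + s
  ad <- d$group == "AD"
  status <- tibble::tibble(
    subject = d$subject[ad],
    value = d$value[ad],
    status = ifelse(v[ad] >= threshold, "AD+", "AD-")
  )
  structure(
    list(marker = marker, flipped = flip, ref_mean = m, ref_sd = s,
         threshold = threshold, status = status,
         n_pos = sum(status$status == "AD+"), n_neg = sum(status$status == "AD-")),
    class = "eeg_strat"
  )
}

#' @export
print.eeg_strat <- function(x, ...) {
  cat(sprintf("<eeg_strat> %s%s: Nold ref %.4g +/- %.4g, threshold %.4g; AD+ %d, AD- %d\n",
              x$marker, if (x$flipped) " (sign-flipped)" else "",
              x$ref_mean, x$ref_sd, x$threshold, x$n_pos, x$n_neg))
  invisible(x)
}

#' Compare an outcome between the AD+ and AD- subgroups
#'
#' One-tailed Welch t-test of a per-subject outcome (MMSE, normalized GM /
#' WM / CSF volume, ...) between the marker-positive and marker-negative
#' AD subgroups. `tail = "less"` tests the hypothesis that AD+ subjects
#' have lower outcome values (the expected direction for MMSE and GM);
#' `"greater"` the reverse (expected for CSF). A subgroup with fewer than
#' two members makes the comparison not testable (flagged, not an error).
#'
#' @param strat an `eeg_strat`.
#' @param outcome tibble `subject`, `value` (or a named numeric vector).
#' @param tail `"less"` or `"greater"` (AD+ relative to AD-).
#' @return One-row tibble: subgroup means and sizes, `t`, `df`, `p`,
#'   `tail`, `testable`.
#' @export
compare_subgroups <- function(strat, outcome, tail = c("less", "greater")) {
  stopifnot(inherits(strat, "eeg_strat"))
  tail <- match.arg(tail)
  if (is.numeric(outcome) && !is.null(names(outcome))) {
    outcome <- tibble::tibble(subject = names(outcome), value = unname(outcome))
  }
  d <- dplyr::inner_join(strat$status[, c("subject", "status")], outcome, by = "subject")
  d <- d[is.finite(d$value), ]
  xp <- d$value[d$status == "AD+"]; xn <- d$value[d$status == "AD-"]
  if (length(xp) < 2L || length(xn) < 2L) {
    return(tibble::tibble(
      mean_pos = if (length(xp)) mean(xp) else NA_real_,
      mean_neg = if (length(xn)) mean(xn) else NA_real_,
      n_pos = length(xp), n_neg = length(xn),
      t = NA_real_, df = NA_real_, p = NA_real_, tail = tail, testable = FALSE
    ))
  }
  tt <- t.test(xp, xn, alternative = tail)
  tibble::tibble(
    mean_pos = mean(xp), mean_neg = mean(xn),
    n_pos = length(xp), n_neg = length(xn),
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    tail = tail, testable = TRUE
  )
}

#' Normalize brain compartment volumes
#'
#' Divides each compartment volume (gray matter, white matter,
#' cerebrospinal fluid) by the subject's total GM + WM + CSF volume, so the
#' three normalized values are in (0,1) and sum to one; they are invariant
#' to a global rescaling of the raw volumes.
#'
#' @param volumes tibble with columns `gm`, `wm`, `csf` (strictly positive),
#'   and optionally `subject`.
#' @return The input tibble with added `gm_norm`, `wm_norm`, `csf_norm`.
#' @export
normalize_volumes <- function(volumes) {
  stopifnot(is.data.frame(volumes), all(c("gm", "wm", "csf") %in% names(volumes)))
  bad <- which(!(volumes$gm > 0 & volumes$wm > 0 & volumes$csf > 0))
  if (length(bad)) {
    who <- if ("subject" %in% names(volumes)) volumes$subject[bad] else bad
    abort(paste("non-positive volume for subject(s):", paste(who, collapse = ", ")))
  }
  tot <- volumes$gm + volumes$wm + volumes$csf
  dplyr::mutate(tibble::as_tibble(volumes),
                gm_norm = .data$gm / tot, wm_norm = .data$wm / tot,
                csf_norm = .data$csf / tot)
}
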