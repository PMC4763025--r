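#' Receiver operating characteristic curve of one marker
#'
#' Thresholds are placed at all midpoints between adjacent distinct pooled
#' values, plus -Inf/+Inf sentinels. The orientation is chosen
#' automatically so that the area under the curve is at least 0.5 (a flip
#' is recorded); a subject exactly at the positivity threshold counts
#' positive (the ">=" rule, consistent with the AD+ stratification rule).
#'
#' @param values numeric marker values, one per subject.
#' @param labels group labels aligned with `values`.
#' @param positive the label of the positive (patient) class, default `"AD"`.
#' @return Object of class `eeg_roc`: tibble of
#'   (threshold, sensitivity, specificity), orientation flag `flipped`,
#'   group sizes.
#' @export
roc_curve <- function(values, labels, positive = "AD") {
  stopifnot(length(values) == length(labels))
  labels <- as.character(labels)
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  if (length(pos) == 0L || length(neg) == 0L) {
    abort("ROC needs both a positive and a negative group")
  }
  if (any(!is.finite(c(pos, neg)))) abort("non-finite marker values")
  raw_auc <- pairwise_auc(pos, neg)
  flipped <- raw_auc < 0.5
  if (flipped) { pos <- -pos; neg <- -neg }
  v <- sort(unique(c(pos, neg)))
  th <- c(-Inf, if (length(v) > 1) (head(v, -1) + tail(v, -1)) / 2, Inf)
  sens <- vapply(th, function(t) mean(pos >= t), 0)
  spec <- vapply(th, function(t) mean(neg < t), 0)
  structure(
    list(points = tibble::tibble(threshold = th, sensitivity = sens, specificity = spec),
         flipped = flipped, n_pos = length(pos), n_neg = length(neg),
         positive = positive),
    class = "eeg_roc"
  )
}

# Tie-adjusted pairwise-comparison probability (rank-sum form).
pairwise_auc <- function(pos, neg) {
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' @export
print.eeg_roc <- function(x, ...) {
  cat(sprintf("<eeg_roc> %d thresholds, n_pos=%d n_neg=%d, AUROC=%.3f%s\n",
              nrow(x$points), x$n_pos, x$n_neg, auroc(x),
              if (x$flipped) " (orientation flipped)" else ""))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Trapezoidal area over the (1 - specificity, sensitivity) path. With
#' midpoint thresholds and the ">=" positivity rule this equals the
#' tie-adjusted pairwise-comparison probability (ties counted one half)
#' exactly.
#'
#' @param curve an `eeg_roc`.
#' @return AUROC in \[0,1\].
#' @export
auroc <- function(curve) {
  stopifnot(inherits(curve, "eeg_roc"))
  fpr <- 1 - curve$points$specificity
  sens <- curve$points$sensitivity
  o <- order(fpr, sens)
  fpr <- fpr[o]; sens <- sens[o]
  sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
}

#' Operating point of an ROC curve
#'
#' The threshold maximizing the Youden index J = sensitivity +
#' specificity - 1; ties are broken by higher specificity, then by lower
#' threshold (on the oriented scale). Accuracy is defined as the mean of
#' sensitivity and specificity at that point.
#'
#' @param curve an `eeg_roc`.
#' @return One-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `accuracy`, `youden`.
#' @export
operating_point <- function(curve) {
  stopifnot(inherits(curve, "eeg_roc"))
  p <- curve$points
  J <- p$sensitivity + p$specificity - 1
  best <- order(-J, -p$specificity, p$threshold)[1]
  tibble::tibble(
    threshold = p$threshold[best],
    sensitivity = p$sensitivity[best],
    specificity = p$specificity[best],
    accuracy = (p$sensitivity[best] + p$specificity[best]) / 2,
    youden = J[best]
  )
}

#' Evaluate screened markers by ROC analysis
#'
#' Runs an ROC analysis for every marker that passed the screen, reports
#' sensitivity, specificity, accuracy (their mean) and AUROC at the Youden
#' operating point, and flags markers whose AUROC strictly exceeds
#' `auroc_threshold` (default 0.70, the conventional floor of a "moderate"
#' classification rate). Summaries are sorted by AUROC, best first.
#'
#' @param markers long marker table from [build_markers()].
#' @param screen an `eeg_screen` computed on the same table.
#' @param meta tibble with `subject` and `group`.
#' @param auroc_threshold selection threshold on AUROC (strict `>`).
#' @return Tibble of class `eeg_roc_summary`: `marker`, `auroc`,
#'   `sensitivity`, `specificity`, `accuracy`, `threshold`, `flipped`,
#'   `selected`, sorted by AUROC descending. The top row is the best
#'   marker.
#' @export
evaluate_markers <- function(markers, screen, meta, auroc_threshold = 0.70) {
  stopifnot(inherits(screen, "eeg_screen"))
  keep <- screen$marker[screen$selected]
  if (length(keep) == 0L) {
    warn("no markers passed the screen; empty ROC report")
    out <- tibble::tibble(marker = character(), auroc = double(),
                          sensitivity = double(), specificity = double(),
                          accuracy = double(), threshold = double(),
                          flipped = logical(), selected = logical())
    class(out) <- c("eeg_roc_summary", class(out))
    return(out)
  }
  meta <- dplyr::distinct(meta[, c("subject", "group")])
  out <- purrr::map_dfr(keep, function(mk) {
    d <- dplyr::inner_join(markers[markers$marker == mk, ], meta, by = "subject")
    rc <- roc_curve(d$value, d$group)
    op <- operating_point(rc)
    tibble::tibble(marker = mk, auroc = auroc(rc),
                   sensitivity = op$sensitivity, specificity = op$specificity,
                   accuracy = op$accuracy, threshold = op$threshold,
                   flipped = rc$flipped)
  })
  out <- dplyr::arrange(out, dplyr::desc(.data$auroc))
  out$selected <- out$auroc > auroc_threshold
  attr(out, "auroc_threshold") <- auroc_threshold
  attr(out, "best") <- out$marker[1]
  class(out) <- c("eeg_roc_summary", class(out))
  out
}
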