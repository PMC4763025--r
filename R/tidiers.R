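#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an ROC curve into its operating points
#' @param x an `eeg_roc`.
#' @param ... unused.
#' @return Tibble of (threshold, sensitivity, specificity, fpr).
#' @method tidy eeg_roc
#' @export
tidy.eeg_roc <- function(x, ...) {
  dplyr::mutate(x$points, fpr = 1 - .data$specificity)
}

#' @rdname tidy.eeg_roc
#' @method glance eeg_roc
#' @export
glance.eeg_roc <- function(x, ...) {
  op <- operating_point(x)
  tibble::tibble(auroc = auroc(x), sensitivity = op$sensitivity,
                 specificity = op$specificity, accuracy = op$accuracy,
                 threshold = op$threshold, flipped = x$flipped,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy marker screening results
#' @param x an `eeg_screen`.
#' @param ... unused.
#' @method tidy eeg_screen
#' @export
tidy.eeg_screen <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.eeg_screen
#' @method glance eeg_screen
#' @export
glance.eeg_screen <- function(x, ...) {
  tibble::tibble(n_markers = nrow(x), n_selected = sum(x$selected),
                 alpha = attr(x, "alpha"))
}

#' Tidy a marker ROC summary report
#' @param x an `eeg_roc_summary`.
#' @param ... unused.
#' @method tidy eeg_roc_summary
#' @export
tidy.eeg_roc_summary <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.eeg_roc_summary
#' @method glance eeg_roc_summary
#' @export
glance.eeg_roc_summary <- function(x, ...) {
  tibble::tibble(n_evaluated = nrow(x), n_selected = sum(x$selected),
                 best_marker = if (nrow(x)) x$marker[1] else NA_character_,
                 best_auroc = if (nrow(x)) x$auroc[1] else NA_real_,
                 auroc_threshold = attr(x, "auroc_threshold"))
}

#' Tidy an AD+/AD- stratification
#' @param x an `eeg_strat`.
#' @param ... unused.
#' @method tidy eeg_strat
#' @export
tidy.eeg_strat <- function(x, ...) x$status

#' @rdname tidy.eeg_strat
#' @method glance eeg_strat
#' @export
glance.eeg_strat <- function(x, ...) {
  tibble::tibble(marker = x$marker, ref_mean = x$ref_mean, ref_sd = x$ref_sd,
                 threshold = x$threshold, flipped = x$flipped,
                 n_ad_pos = x$n_pos, n_ad_neg = x$n_neg)
}
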