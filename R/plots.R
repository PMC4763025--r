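#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline geom_point
#'   geom_col labs theme_minimal scale_y_log10 facet_wrap geom_hline coord_equal
#' @export
ggplot2::autoplot

#' Plot an ROC curve
#'
#' Sensitivity against 1 - specificity with the chance diagonal and the
#' Youden operating point highlighted.
#'
#' @param object an `eeg_roc`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot eeg_roc
#' @export
autoplot.eeg_roc <- function(object, ...) {
  pts <- tidy(object)
  op <- operating_point(object)
  ggplot(pts, aes(x = .data$fpr, y = .data$sensitivity)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_line(colour = "#2c7fb8") +
    geom_point(data = tibble::tibble(fpr = 1 - op$specificity, sensitivity = op$sensitivity),
               colour = "#d95f02", size = 2.5) +
    coord_equal() +
    labs(x = "1 - specificity", y = "sensitivity",
         title = sprintf("ROC (AUROC = %.3f)", auroc(object))) +
    theme_minimal()
}

#' Plot power spectra
#'
#' One PSD trace per signal on a log power scale.
#'
#' @param object an `eeg_spectra`.
#' @param f_max upper frequency limit (Hz), default 45.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot eeg_spectra
#' @export
autoplot.eeg_spectra <- function(object, f_max = 45, ...) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(t(object$values)), freq = object$freqs),
    -"freq", names_to = "signal", values_to = "psd"
  )
  df <- df[df$freq <= f_max & df$freq > 0, ]
  ggplot(df, aes(x = .data$freq, y = .data$psd, group = .data$signal)) +
    geom_line(alpha = 0.5, colour = "#2c7fb8") +
    scale_y_log10() +
    labs(x = "frequency (Hz)", y = "power density", title = "Welch PSD") +
    theme_minimal()
}

#' Plot a marker ROC summary
#'
#' AUROC per evaluated marker with the moderate-classification threshold.
#'
#' @param object an `eeg_roc_summary`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot eeg_roc_summary
#' @export
autoplot.eeg_roc_summary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$marker <- factor(df$marker, levels = rev(df$marker))
  thr <- attr(object, "auroc_threshold") %||% 0.70
  ggplot(df, aes(x = .data$auroc, y = .data$marker, fill = .data$selected)) +
    geom_col(width = 0.7) +
    geom_vline_auroc(thr) +
    labs(x = "AUROC", y = NULL, fill = sprintf("AUROC > %.2f", thr)) +
    theme_minimal()
}

geom_vline_auroc <- function(thr) {
  ggplot2::geom_vline(xintercept = thr, linetype = "dashed", colour = "grey40")
}
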