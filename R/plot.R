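# ggplot2 views of the package's result types.

#' Plot spectra
#'
#' @param object An `fgrs_spectra` tibble.
#' @param alpha Line transparency (many overlaid spectra).
#' @param ... Unused.
#' @return A ggplot object: intensity vs Raman shift, colored by class
#'   label.
#' @export
autoplot.fgrs_spectra <- function(object, alpha = 0.3, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wavenumber, .data$intensity,
                                       group = .data$sample_id,
                                       colour = .data$label)) +
    ggplot2::geom_line(alpha = alpha) +
    ggplot2::labs(x = expression("Raman shift (" * cm^-1 * ")"),
                  y = "intensity (a.u.)", colour = "class") +
    ggplot2::theme_minimal()
}

#' Plot a group summary as mean with one-SD shade
#'
#' @param object A [group_mean_sd()] summary.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fgrs_group_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wavenumber, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression("Raman shift (" * cm^-1 * ")"),
                  y = "intensity (a.u.)",
                  title = sprintf("%s (n = %d)", attr(object, "label"),
                                  attr(object, "n"))) +
    ggplot2::theme_minimal()
}

#' Plot a feature mask over the difference spectrum threshold
#'
#' @param object A [double_sd_mask()] result.
#' @param ... Unused.
#' @return A ggplot object marking selected channels.
#' @export
autoplot.fgrs_feature_mask <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wavenumber,
                                       as.integer(.data$selected))) +
    ggplot2::geom_col(width = diff(range(object$wavenumber)) / nrow(object),
                      fill = "grey30") +
    ggplot2::labs(x = expression("Raman shift (" * cm^-1 * ")"),
                  y = "selected",
                  title = sprintf("%d channels above the threshold",
                                  attr(object, "n_selected"))) +
    ggplot2::theme_minimal()
}

#' Plot band effect sizes
#'
#' @param object A [band_stats_table()] result.
#' @param ... Unused.
#' @return A ggplot object: |d| per band, colored by molecular assignment,
#'   starred by rank-sum significance.
#' @export
autoplot.fgrs_band_stats <- function(object, ...) {
  df <- as_tibble(object)
  df$band <- factor(df$band, levels = df$band)
  ggplot2::ggplot(df, ggplot2::aes(.data$band, .data$d_abs,
                                   fill = .data$assignment)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), vjust = -0.2) +
    ggplot2::labs(x = expression("Raman shift (" * cm^-1 * ")"),
                  y = "|Cohen's d|", fill = "assignment") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot an ROC curve
#'
#' @param object An [evaluate_predictions()] result.
#' @param ... Unused.
#' @return A ggplot object with the AUC in the title.
#' @export
autoplot.fgrs_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.2f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot the experiment grid
#'
#' @param object A [run_experiment()] table.
#' @param ... Unused.
#' @return A ggplot object: accuracy by scenario, faceted by feature mode,
#'   colored by kernel.
#' @export
autoplot.fgrs_experiment <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$scenario, .data$accuracy,
                                   fill = .data$kernel)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~feature_mode) +
    ggplot2::labs(x = NULL, y = "accuracy (%)", fill = "kernel") +
    ggplot2::theme_minimal()
}
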