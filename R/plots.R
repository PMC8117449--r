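# ggplot2 visualizations for the main result types.

#' Plot an ROC curve
#'
#' @param object A `fetdki_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fetdki_roc
#' @export
autoplot.fetdki_roc <- function(object, ...) {
  df <- object$curve
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC = %.3f (95%% CI %.3f-%.3f)",
                      object$auc, object$auc_ci[1], object$auc_ci[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot a lesion relative-frequency histogram
#'
#' Raw relative frequencies as bars with the moving-average-smoothed curve
#' overlaid.
#'
#' @param object A `fetdki_histogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fetdki_histogram
#' @export
autoplot.fetdki_histogram <- function(object, ...) {
  df <- tidy.fetdki_histogram(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$rel_freq),
                      fill = "steelblue", alpha = 0.5, width = diff(df$mid[1:2])) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), color = "firebrick",
                       linewidth = 0.7) +
    ggplot2::labs(
      x = if (object$family == "dt") {
        expression(paste("Diffusivity (", mu, m^2, "/ms)"))
      } else "Kurtosis",
      y = "Relative frequency"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a time-activity curve
#'
#' @param tac Tibble from [extract_tac()].
#' @param late_window Shaded late-phase window in minutes.
#' @return A ggplot.
#' @export
plot_tac <- function(tac, late_window = c(20, 50)) {
  ggplot2::ggplot(tac, ggplot2::aes(x = .data$mid_min, y = .data$suv)) +
    ggplot2::annotate("rect", xmin = late_window[1], xmax = late_window[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.08, fill = "blue") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time post-injection (min)", y = "SUV") +
    ggplot2::theme_minimal()
}

#' Plot the per-feature group separation of a cohort
#'
#' Boxplots of each schema feature by diagnosis group, faceted with free
#' scales; a quick qualitative view of the direction of group differences.
#'
#' @param cohort Feature tibble with `group`.
#' @param features Feature subset (default: all schema features present).
#' @return A ggplot.
#' @export
plot_cohort_features <- function(cohort,
                                 features = intersect(FEATURE_SCHEMA,
                                                      names(cohort))) {
  long <- tidyr::pivot_longer(cohort[, c("group", features)],
                              -"group", names_to = "feature")
  long$feature <- factor(long$feature, levels = features)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
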