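#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline geom_point
#'   geom_vline geom_segment geom_errorbar geom_hline labs facet_wrap
#'   theme_minimal position_dodge
NULL

#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' Draws the ROC polygon (sensitivity against 1 - specificity) with the
#' chance diagonal; the AUC and its confidence interval appear in the
#' subtitle.
#'
#' @param object A `lace_roc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lace_roc
#' @export
autoplot.lace_roc <- function(object, ...) {
  df <- dplyr::arrange(object$curve, dplyr::desc(.data$threshold))
  ggplot(df, aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line() +
    geom_point(size = 0.8) +
    labs(
      x = "1 - specificity", y = "Sensitivity",
      subtitle = sprintf("AUC = %.1f%% (%d%% CI %.1f-%.1f)",
                         100 * object$auc, round(100 * object$conf_level),
                         100 * object$auc_ci[1], 100 * object$auc_ci[2])
    ) +
    theme_minimal()
}

#' Plot a two-graph ROC analysis
#'
#' Sensitivity and specificity as functions of the decision threshold, with
#' the equal-error crossing marked and the intermediate range drawn as a
#' bar at the accuracy level.
#'
#' @param object A `two_graph` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot two_graph
#' @export
autoplot.two_graph <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curve, c("sensitivity", "specificity"),
                              names_to = "measure", values_to = "value")
  ggplot(long, aes(x = .data$threshold, y = .data$value,
                   colour = .data$measure)) +
    geom_line() +
    geom_point(size = 0.8) +
    geom_vline(xintercept = object$theta0, linetype = "dotted") +
    geom_hline(yintercept = object$level, linetype = "dashed",
               colour = "grey60") +
    geom_segment(aes(x = object$ir_lower, xend = object$ir_upper,
                     y = object$level, yend = object$level),
                 inherit.aes = FALSE, colour = "red", linewidth = 1.2) +
    labs(
      x = "Score threshold", y = "Sensitivity / specificity",
      colour = NULL,
      subtitle = sprintf("theta0 = %.1f; IR %d%% = %.1f-%.1f",
                         object$theta0, round(100 * object$level),
                         object$ir_lower, object$ir_upper)
    ) +
    theme_minimal()
}

#' Band-wise AUC and threshold summaries of a study
#'
#' `plot_band_auc()` shows each stratum's AUC with its confidence interval,
#' facetted by outcome; `plot_band_thresholds()` shows the equal-error
#' threshold with its intermediate range.
#'
#' @param study A `lace_study` object.
#' @return A ggplot.
#' @export
plot_band_auc <- function(study) {
  stopifnot(inherits(study, "lace_study"))
  df <- tidy(study)
  df$stratum <- factor(df$stratum, levels = unique(df$stratum))
  ggplot(df, aes(x = .data$stratum, y = 100 * .data$auc)) +
    geom_point() +
    geom_errorbar(aes(ymin = 100 * .data$auc_ci_lower,
                      ymax = 100 * .data$auc_ci_upper), width = 0.2) +
    geom_hline(yintercept = 50, linetype = "dashed", colour = "grey60") +
    facet_wrap(~outcome) +
    labs(x = NULL, y = "AUC (%)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_band_auc
#' @export
plot_band_thresholds <- function(study) {
  stopifnot(inherits(study, "lace_study"))
  df <- tidy(study)
  df$stratum <- factor(df$stratum, levels = unique(df$stratum))
  ggplot(df, aes(x = .data$stratum, y = .data$theta0)) +
    geom_point() +
    geom_errorbar(aes(ymin = .data$ir_lower, ymax = .data$ir_upper),
                  width = 0.2) +
    facet_wrap(~outcome) +
    labs(x = NULL, y = "Equal-error threshold (with intermediate range)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
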