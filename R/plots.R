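# ggplot2 visualisations for the result types.

#' Plot an ROC curve
#'
#' @param object a [roc_analysis()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.plqct_roc <- function(object, ...) {
  df <- object$curve
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(direction = "hv", linewidth = 0.8) +
    ggplot2::annotate(
      "text", x = 0.65, y = 0.1,
      label = sprintf("AUC %.3f (%.3f-%.3f)",
                      object$auc, object$ci95_low, object$ci95_high)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("Criterion %s %.1f mg/cc (J = %.2f)",
                                  object$criterion_direction,
                                  object$associated_criterion,
                                  object$youden_j)) +
    ggplot2::theme_minimal()
}

#' Plot a 3x3 diagnostic confusion matrix
#'
#' @param object a [confusion_matrix_3x3()] result.
#' @param ... unused.
#' @return a ggplot (tile heat map with counts).
#' @export
autoplot.plqct_confusion <- function(object, ...) {
  df <- as.data.frame(as.table(object$matrix))
  names(df) <- c("reference", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$reference,
                                   fill = .data$n)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev(bmd_categories())) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "QCT prediction", y = "DXA reference",
                  title = sprintf("Agreement %.1f%% (n = %d)",
                                  100 * object$agreement, object$n)) +
    ggplot2::theme_minimal()
}

#' Plot the age-stratified BMD trend
#'
#' Mean vBMD (with SD ribbon where defined) per decade bin, by sex.
#'
#' @param strata output of [age_stratified_bmd()], or a cohort tibble (which
#'   is stratified first).
#' @param value column summarized when a cohort is given.
#' @return a ggplot.
#' @export
plot_age_trend <- function(strata, value = "qct_vbmd") {
  if (!all(c("age_bin", "sex", "mean") %in% names(strata))) {
    strata <- age_stratified_bmd(strata, value = value)
  }
  df <- dplyr::filter(strata, .data$n > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_bin, y = .data$mean,
                                   colour = .data$sex, group = .data$sex)) +
    ggplot2::geom_ribbon(
      data = dplyr::filter(df, !is.na(.data$sd)),
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd,
                   fill = .data$sex),
      alpha = 0.15, colour = NA) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Age group (years)", y = "Trabecular vBMD (mg/cc)",
                  colour = "Sex", fill = "Sex") +
    ggplot2::theme_minimal()
}
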