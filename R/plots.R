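#' Plot a ROC curve
#'
#' Draws the empirical ROC curve of an evaluated parameter with the chance
#' diagonal and the operating point of the selected cutoff.
#'
#' @param object a `pet_roc` from [roc_evaluate()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot pet_roc
#' @export
autoplot.pet_roc <- function(object, ...) {
  curve <- object$curve
  m <- confusion_metrics(object$cutoff)
  op <- tibble::tibble(fpr = 1 - m$specificity / 100,
                       tpr = m$sensitivity / 100)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::geom_point(data = op, colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = object$parameter,
      subtitle = sprintf("AUC %.2f [%.2f-%.2f], cutoff %.4g",
                         object$auc$auc, object$auc$ci_lo, object$auc$ci_hi,
                         object$cutoff$cutoff),
      x = "false positive rate (1 - specificity)",
      y = "true positive rate (sensitivity)"
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of AUCs across parameters
#'
#' Point-range display of every parameter's AUC and 95% CI from a pipeline
#' run, ordered by AUC, with the chance level marked.
#'
#' @param run a `pet_run` from [run_pet_response()].
#' @return A ggplot.
#' @export
plot_auc_forest <- function(run) {
  stopifnot(inherits(run, "pet_run"))
  df <- dplyr::mutate(run$report,
                      parameter = stats::reorder(.data$parameter, .data$auc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$auc, y = .data$parameter)) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lo,
                                          xmax = .data$ci_hi)) +
    ggplot2::labs(x = "AUC (DeLong 95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
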