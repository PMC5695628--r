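#' @importFrom ggplot2 ggplot aes geom_point geom_abline geom_line
#'   geom_ribbon geom_errorbar geom_col labs theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Predicted vs measured plot for LOO cross-validation
#'
#' @param object A `gp_loo` result.
#' @param ... Ignored.
#' @export
autoplot.gp_loo <- function(object, ...) {
  d <- object$predictions
  ggplot(d, aes(x = .data$y, y = .data$.pred)) +
    geom_errorbar(aes(ymin = .data$.pred - .data$.pred_sd,
                      ymax = .data$.pred + .data$.pred_sd),
                  color = "grey70", width = 0) +
    geom_point(alpha = 0.7) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(x = "measured (log2)", y = "predicted (log2)",
         title = sprintf("Leave-one-out predictions (R = %.2f)",
                         object$r_pearson)) +
    theme_minimal()
}

#' Learning-curve plot
#'
#' @param object A [learning_curve()] result.
#' @param ... Ignored.
#' @export
autoplot.learning_curve <- function(object, ...) {
  s <- object$summary
  ggplot(s, aes(x = .data$size, y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$mean - .data$se,
                    ymax = .data$mean + .data$se), alpha = 0.2) +
    geom_line() + geom_point() +
    labs(x = "training-set size",
         y = if (object$metric == "auc") "test AUC" else "test Pearson R") +
    theme_minimal()
}

#' ROC curve plot
#'
#' @param points Tibble from [roc_points()].
#' @param auc Optional AUC to print in the title.
#' @export
plot_roc <- function(points, auc = NULL) {
  ggplot(points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_line() +
    geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey60") +
    labs(x = "false positive rate", y = "true positive rate",
         title = if (!is.null(auc)) sprintf("ROC (AUC = %.3f)", auc)) +
    theme_minimal()
}

#' Feature-weight plot along the alignment
#'
#' Bars at feature positions (contacts at their first position), signed by
#' weight and colored by feature type.
#'
#' @param mapped Tibble from [map_weights()].
#' @export
plot_weights <- function(mapped) {
  ggplot(mapped, aes(x = .data$pos_i, y = .data$weight,
                     fill = .data$type)) +
    geom_col(position = "identity", alpha = 0.8) +
    labs(x = "alignment position", y = "weight (log2 units)",
         fill = NULL) +
    theme_minimal()
}
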