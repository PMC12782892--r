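# ggplot2 graphics for the result types.

#' Plot per-fold cross-validation accuracy
#'
#' Per-fold Pearson accuracies as points with the mean as a dashed line.
#'
#' @param object A `gap_cv` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gap_cv
#' @export
autoplot.gap_cv <- function(object, ...) {
  df <- dplyr::mutate(object$folds, fold = factor(.data$fold))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold, y = .data$r)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$mean_r, linetype = "dashed") +
    ggplot2::labs(
      x = "Fold", y = "Prediction accuracy (Pearson r, GPV vs OPV)",
      title = paste0(object$k, "-fold CV, ", object$mode, " model, ",
                     object$trait),
      subtitle = paste0("mean r = ", round(object$mean_r, 4))
    )
}

#' Plot estimated genotype effects per marker
#'
#' Deviations of genotype-class means from the grand mean, faceted by
#' marker; low-support classes are hollow.
#'
#' @param object A `gap_effects` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gap_effects
#' @export
autoplot.gap_effects <- function(object, ...) {
  ggplot2::ggplot(object$effects,
                  ggplot2::aes(x = .data$genotype, y = .data$effect)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$low_support), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                name = "low support") +
    ggplot2::facet_wrap(ggplot2::vars(.data$marker_id), scales = "free_x") +
    ggplot2::labs(x = "Genotype", y = "Effect (deviation from grand mean)",
                  title = paste("Genotype effects on", object$trait))
}

#' Scatter of predicted versus observed values
#'
#' The regression-style GPV/OPV scatter used to display prediction
#' accuracy, with the least-squares line and the Pearson r annotated.
#'
#' @param predictions Data frame with columns `gpv` and `opv` (e.g. a
#'   [predict.gap_model()] result joined to observed phenotypes).
#' @param trait Optional trait label for the title.
#' @return A ggplot object.
#' @export
plot_gpv_opv <- function(predictions, trait = NULL) {
  r <- prediction_accuracy(predictions)
  ggplot2::ggplot(predictions,
                  ggplot2::aes(x = .data$gpv, y = .data$opv)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "Genotype predicted value (GPV)",
      y = "Observed phenotype value (OPV)",
      title = if (is.null(trait)) "GPV vs OPV" else
        paste("GPV vs OPV,", trait),
      subtitle = paste0("Pearson r = ", round(r, 4))
    )
}

#' Plot a storage softening series
#'
#' Monthly measurements per replicate with the acceptability threshold.
#'
#' @param series_df Long data frame `replicate_id`, `month`, `value`.
#' @param threshold Optional threshold line (e.g. 7.0 for firmness).
#' @return A ggplot object.
#' @export
plot_storage_series <- function(series_df, threshold = NULL) {
  p <- ggplot2::ggplot(series_df,
                       ggplot2::aes(x = .data$month, y = .data$value,
                                    group = .data$replicate_id)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Month of cold storage", y = "Measurement (kg/cm2)")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}
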