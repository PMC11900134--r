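# ggplot2 views of the main result types.

#' Plot a compound profile
#'
#' Predicted pChEMBL per receptor/site entry, coloured by the argmax
#' activity class, with the docking score as a secondary label when present.
#'
#' @param profile A [build_profile()] tibble.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = paste(.data$receptor_id, .data$site_mode, sep = "\n"),
                               y = .data$predicted_pchembl,
                               fill = factor(.data$predicted_class))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "predicted pChEMBL",
                  fill = "activity class",
                  title = unique(profile$compound_id)[1]) +
    ggplot2::theme_minimal()
}

#' Plot a fragment importance report
#'
#' Split-gain of the top fingerprint bits, labelled by their decoded
#' fragment SMILES.
#'
#' @param report An [importance_report()] tibble.
#' @return A ggplot object.
#' @export
plot_importance <- function(report) {
  report$label <- sprintf("bit %d\n%s", report$bit, report$fragment_smiles)
  ggplot2::ggplot(report,
                  ggplot2::aes(x = stats::reorder(.data$label, .data$gain),
                               y = .data$gain)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "split gain") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Cross-validation metrics of a model bundle
#'
#' @param object A `gpcr_model_bundle`.
#' @param ... Unused.
#' @return A ggplot object showing per-fold CV accuracy and RMSE.
#' @method autoplot gpcr_model_bundle
#' @export
autoplot.gpcr_model_bundle <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$fold, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::labs(title = sprintf("%s (%s): 10-fold CV", object$receptor_id,
                                  object$site_mode),
                  x = "fold", y = NULL) +
    ggplot2::theme_minimal()
}
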