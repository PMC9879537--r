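#' Plot a ROC curve
#'
#' @param ... Named [roc_auc()] results (one or more).
#' @return A ggplot.
#' @export
plot_roc <- function(...) {
  rocs <- list(...)
  if (is.null(names(rocs)) || any(!nzchar(names(rocs)))) {
    names(rocs) <- paste0("classifier", seq_along(rocs))
  }
  df <- dplyr::bind_rows(
    purrr::imap(rocs, function(r, nm) {
      dplyr::mutate(r$curve,
                    classifier = sprintf("%s (AUC %.2f)", nm, r$auc))
    }))
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr,
                                   colour = .data$classifier)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a precision-recall curve
#'
#' @param ... Named [precision_recall()] results.
#' @return A ggplot.
#' @export
plot_precision_recall <- function(...) {
  prs <- list(...)
  if (is.null(names(prs)) || any(!nzchar(names(prs)))) {
    names(prs) <- paste0("classifier", seq_along(prs))
  }
  df <- dplyr::bind_rows(
    purrr::imap(prs, function(r, nm) {
      dplyr::mutate(r$curve,
                    classifier = sprintf("%s (AP %.2f)", nm,
                                         r$average_precision))
    }))
  ggplot2::ggplot(df, ggplot2::aes(.data$recall, .data$precision,
                                   colour = .data$classifier)) +
    ggplot2::geom_step(linewidth = 0.7, direction = "vh") +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Distribution of Expression Scores by provenance
#'
#' Histogram of final ES values, split into out-of-fold training
#' positives and full-model query pairs.
#'
#' @param object An `es_table`.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.es_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$es, fill = .data$provenance)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.7,
                            position = "identity") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "Expression Score", y = "Gene pairs",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot expresso-group size distribution
#'
#' Component-size histogram of a fractionation run (orthogroup sizes vs
#' expresso-group sizes).
#'
#' @param summary Result of [summarize_patterns()].
#' @return A ggplot.
#' @export
plot_fractionation_sizes <- function(summary) {
  ggplot2::ggplot(summary$component_sizes,
                  ggplot2::aes(factor(.data$size), .data$n_components)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Expresso-group size (genes)",
                  y = "Number of groups") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
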