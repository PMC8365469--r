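#' Plot a cross-validation report
#'
#' Per-fold AUC and AUPR values by repeat, with the per-repeat mean
#' overlaid — the visual analogue of the per-experiment summary table.
#'
#' @param object A [cross_validate()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object, ...) {
  long <- object$folds |>
    tidyr::pivot_longer(c("auc", "aupr"),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = toupper(.data$metric))
  means <- long |>
    dplyr::group_by(.data$repeat_id, .data$metric) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$repeat_id), y = .data$value
  )) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 1) +
    ggplot2::geom_point(data = means, colour = "red", size = 2) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(
      x = "Repeat (fresh negative sample)", y = "Held-out fold metric",
      title = "Repeated negative-sampling cross-validation"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a walk profile
#'
#' Gene probabilities in rank order, seed genes highlighted, probability
#' on a log scale — shows how far the restart walk spreads mass beyond
#' the seeds at the chosen restart probability.
#'
#' @param object A `walk_profile`.
#' @param seeds Optional character vector of seed genes to highlight.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.walk_profile <- function(object, seeds = NULL, ...) {
  df <- tidy(object) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      is_seed = .data$gene %in% (seeds %||% names(which(object$p0 > 0)))
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$rank, y = .data$probability, colour = .data$is_seed
  )) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(
      x = "Gene rank", y = "Walk probability", colour = "Seed",
      title = sprintf("Restart walk profile (gamma = %.2g)", object$gamma)
    ) +
    ggplot2::theme_minimal()
}

#' Compare ROC curves for one or more score vectors
#'
#' Accepts a named list of score vectors over the same items — e.g. this
#' method next to externally computed baseline scores — and draws their
#' ROC curves with per-method AUC in the legend.
#'
#' @param scores_list Named list of numeric score vectors, or one vector.
#' @param labels Binary labels shared by all score vectors.
#' @return A ggplot object.
#' @export
plot_roc_curves <- function(scores_list, labels) {
  if (!is.list(scores_list)) scores_list <- list(scores = scores_list)
  df <- purrr::imap_dfr(scores_list, function(s, name) {
    dplyr::mutate(
      roc_points(s, labels),
      method = sprintf("%s (AUC %.3f)", name, roc_auc(s, labels))
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$fpr, y = .data$tpr, colour = .data$method
  )) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Compare precision--recall curves for one or more score vectors
#'
#' @inheritParams plot_roc_curves
#' @return A ggplot object.
#' @export
plot_pr_curves <- function(scores_list, labels) {
  if (!is.list(scores_list)) scores_list <- list(scores = scores_list)
  df <- purrr::imap_dfr(scores_list, function(s, name) {
    dplyr::mutate(
      pr_points(s, labels),
      method = sprintf("%s (AUPR %.3f)", name, pr_auc(s, labels))
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$recall, y = .data$precision, colour = .data$method
  )) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(x = "Recall", y = "Precision", colour = NULL) +
    ggplot2::theme_minimal()
}
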