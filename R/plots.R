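#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot patient flow through a pathway
#'
#' Stacked bars of positive / negative / progressed counts per stage.
#'
#' @param object A [build_flowchart()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot flowchart_data
#' @export
autoplot.flowchart_data <- function(object, ...) {
  positive <- attr(object, "positive") %||% "positive"
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("stage", "platform",
                                  "classified_positive",
                                  "classified_negative", "progressed")],
    cols = c("classified_positive", "classified_negative", "progressed"),
    names_to = "outcome", values_to = "count")
  long$outcome <- factor(long$outcome,
                         c("classified_positive", "classified_negative",
                           "progressed"),
                         c(positive, "negative", "uncertain"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = factor(.data$stage), y = .data$count,
                               fill = .data$outcome)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_x_discrete(labels = object$platform) +
    ggplot2::labs(x = "stage (platform)", y = "patients",
                  fill = NULL, title = "Patient flow through the pathway") +
    ggplot2::theme_minimal()
}

#' Plot per-patient accuracy strata
#'
#' Tiles of vote-level patient accuracy, patients ordered by classifying
#' stage, then true class, then accuracy.
#'
#' @param object A [build_strata()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot strata_data
#' @export
autoplot.strata_data <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$index, y = .data$platform,
                               fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(. ~ true_class, scales = "free_x",
                        space = "free_x") +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "firebrick",
                                 high = "steelblue") +
    ggplot2::labs(x = "patient", y = "classifying platform",
                  fill = "accuracy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Bubble plot of candidate pathways
#'
#' Cost against balanced accuracy, point size by rank score (smaller score =
#' larger point), shaded by the proportion classified in the first tier.
#'
#' @param object A [build_bubble()] table or a `pathway_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bubble_data
#' @export
autoplot.bubble_data <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$total_cost,
                               y = .data$balanced_accuracy,
                               size = -.data$score,
                               colour = .data$tier_1,
                               label = .data$sequence)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_text(size = 3, vjust = -1.2, show.legend = FALSE) +
    ggplot2::scale_colour_gradient(limits = c(0, 1), low = "grey80",
                                   high = "darkgreen") +
    ggplot2::labs(x = "total cost", y = "balanced accuracy",
                  colour = "tier 1\nproportion", size = "-score") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.bubble_data
#' @method autoplot pathway_comparison
#' @export
autoplot.pathway_comparison <- function(object, ...) {
  autoplot.bubble_data(build_bubble(object), ...)
}

#' Plot a threshold sweep
#'
#' Balanced accuracy and total cost as functions of the confidence
#' threshold.
#'
#' @param object A [threshold_sweep()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot threshold_sweep
#' @export
autoplot.threshold_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- tidyr::pivot_longer(
    df[, c("threshold", "balanced_accuracy", "total_cost")],
    cols = c("balanced_accuracy", "total_cost"),
    names_to = "criterion", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(x = "confidence threshold", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot feature importances of a frozen ensemble
#'
#' @param object A [build_feature_importance()] table.
#' @param top Show the most frequently selected features only. Default 20.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot feature_importance_data
#' @export
autoplot.feature_importance_data <- function(object, top = 20, ...) {
  df <- utils::head(tibble::as_tibble(object), top)
  df$feature <- factor(df$feature, rev(df$feature))
  ggplot2::ggplot(df,
                  ggplot2::aes(x = .data$selection_frequency,
                               y = .data$feature,
                               fill = .data$effect_direction > 0)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "selection frequency", y = NULL,
                  fill = "higher in\npositive class") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
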