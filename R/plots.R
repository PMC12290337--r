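#' Plot a conjoint proportion matrix
#'
#' Heatmap of choice proportions, stimuli ordered gloss-major so each block of
#' adjacent rows/columns shares a gloss level and varies in filter level —
#' the layout in which filter-induced gradients show up inside the blocks.
#'
#' @param object A [proportion_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.proportion_matrix <- function(object, ...) {
  tidy(object) |>
    dplyr::mutate(
      row = (.data$row_gloss - 1) * object$n_filter + .data$row_filter,
      col = (.data$col_gloss - 1) * object$n_filter + .data$col_filter
    ) |>
    ggplot2::ggplot(ggplot2::aes(.data$col, .data$row, fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "stimulus (gloss-major index)",
                  y = "stimulus (gloss-major index)",
                  fill = "P(row glossier)") +
    ggplot2::theme_minimal()
}

#' Plot fitted conjoint scales
#'
#' @param object An [mlcm_fit()].
#' @param ... Unused.
#' @return A ggplot object showing the gloss and filter scale estimates.
#' @export
autoplot.mlcm_fit <- function(object, ...) {
  tidy(object) |>
    dplyr::filter(.data$dimension %in% c("gloss", "filter")) |>
    ggplot2::ggplot(ggplot2::aes(.data$level, .data$estimate,
                                 colour = .data$dimension)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "stimulus level", y = "perceptual scale (noise-SD units)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot aggregated normalized scales
#'
#' Mean normalized scale per level and dimension with ±1 SEM error bars
#' across observers.
#'
#' @param scales Output of [aggregate_scales()].
#' @return A ggplot object.
#' @export
plot_aggregate_scales <- function(scales) {
  ggplot2::ggplot(scales, ggplot2::aes(.data$level, .data$mean,
                                       colour = .data$dimension)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.1) +
    ggplot2::labs(x = "stimulus level", y = "normalized perceptual scale",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the condition-3 prediction regression
#'
#' Observed joint-matching deviation against the deviation predicted from the
#' single-attribute conditions, with the fitted line and the identity.
#'
#' @param object A [predict_condition3()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.condition3_prediction <- function(object, ...) {
  p <- ggplot2::ggplot(object$records,
                       ggplot2::aes(.data$predicted, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "predicted deviation (lattice steps)",
                  y = "observed deviation (lattice steps)") +
    ggplot2::theme_minimal()
  if (!object$regression$degenerate)
    p <- p + ggplot2::geom_abline(slope = object$regression$slope,
                                  intercept = object$regression$intercept)
  p
}
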