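# ggplot2 visualisations for the main result types.

#' Plot windowed heart rate by condition
#'
#' Sliding-window HR traces (subject means with a ribbon of +/- 1 standard
#' error) for the two interventions, the usual way windowed HR results are
#' displayed.
#'
#' @param hr_windows Tibble from the pipeline's `hr$windows` (columns
#'   `subject`, `condition`, `window`, `start_s`, `hr_bpm`).
#' @return A ggplot object.
#' @export
plot_hr_windows <- function(hr_windows) {
  d <- dplyr::summarise(
    dplyr::group_by(hr_windows, .data$condition, .data$window, .data$start_s),
    mean_hr = mean(.data$hr_bpm, na.rm = TRUE),
    se = stats::sd(.data$hr_bpm, na.rm = TRUE) / sqrt(sum(!is.na(.data$hr_bpm))),
    .groups = "drop"
  )
  ggplot2::ggplot(d, ggplot2::aes(
    .data$start_s, .data$mean_hr,
    colour = .data$condition, fill = .data$condition
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_hr - .data$se, ymax = .data$mean_hr + .data$se),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "Window onset (s)", y = "Heart rate (bpm)",
      colour = "Condition", fill = "Condition"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of an inter-network FC matrix
#'
#' @param object An `fc_matrix` from [internetwork_fc()].
#' @param ... Unused.
#' @return A ggplot object (symmetric heatmap of Fisher-z values).
#' @method autoplot fc_matrix
#' @export
autoplot.fc_matrix <- function(object, ...) {
  d <- tidyr::pivot_longer(
    tibble::as_tibble(object$z, rownames = "net_a"),
    -"net_a",
    names_to = "net_b", values_to = "z"
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$net_a, .data$net_b, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "z",
      title = object$session_label
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of group synchronization per edge
#'
#' @param object A tibble from [group_sync()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bh_sync
#' @export
autoplot.bh_sync <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    stats::reorder(.data$target, .data$mean_z), .data$mean_z,
    fill = .data$significant
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Mean Fisher-z FC-HR synchronization") +
    ggplot2::theme_minimal()
}
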