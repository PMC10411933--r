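#' Plot the staircase time-limit trajectories of a block
#'
#' @param trials A trial table with `trial`, `staircase`, `time_limit` (and
#'   optionally `context`).
#' @param highlight_last Number of late trials per staircase to highlight.
#' @return A ggplot.
#' @export
plot_staircase <- function(trials, highlight_last = 40) {
  late <- trials |>
    group_by(dplyr::across(dplyr::any_of(c("context", "staircase")))) |>
    slice_tail(n = highlight_last) |>
    ungroup()
  p <- ggplot2::ggplot(trials,
                       ggplot2::aes(x = .data$trial, y = .data$time_limit,
                                    colour = .data$staircase)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = late, linewidth = 1.2) +
    ggplot2::labs(x = "Trial", y = "Time limit (ms)", colour = "Staircase") +
    ggplot2::theme_minimal()
  if ("context" %in% names(trials)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$context),
                                 scales = "free_x")
  }
  p
}

#' Plot target-aligned endpoints with their error ellipse
#'
#' @param metrics A [trial_metrics()] tibble with `aligned_x`, `aligned_y`.
#' @param coverage Ellipse coverage.
#' @param target_radius Target radius drawn for scale, au.
#' @return A ggplot.
#' @export
plot_endpoints <- function(metrics, coverage = 0.95, target_radius = 0.1) {
  pts <- metrics |>
    filter(!is.na(.data$aligned_x)) |>
    select(x = "aligned_x", y = "aligned_y")
  ell <- error_ellipse(pts, coverage)
  # target drawn at (0, D) in the aligned frame
  D <- mean(metrics$target_distance, na.rm = TRUE)
  th <- seq(0, 2 * pi, length.out = 121)
  target <- tibble(x = target_radius * cos(th),
                   y = D + target_radius * sin(th))
  ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_path(data = ellipse_outline(ell), colour = "red",
                       linewidth = 1) +
    ggplot2::geom_path(data = target, colour = "grey40",
                       linetype = "dashed") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Off-axis (au)", y = "On-axis (au)") +
    ggplot2::theme_minimal()
}

#' Plot learning curves across practice rounds
#'
#' @param rounds A [round_summary()] tibble.
#' @param measures Columns to draw.
#' @return A ggplot.
#' @export
plot_learning_curve <- function(rounds,
                                measures = c("acquire", "reaction",
                                             "primary_mt", "correction",
                                             "dwell")) {
  long <- tidyr::pivot_longer(rounds, dplyr::all_of(measures),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$round, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y") +
    ggplot2::labs(x = "Round", y = "Median (ms)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.aimkin_fitts <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$id_e, .data$mt)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope, colour = "red") +
    ggplot2::labs(x = "Effective index of difficulty (bits)",
                  y = "Movement time (ms)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.aimkin_ellipse <- function(object, ...) {
  ggplot2::ggplot(ellipse_outline(object), ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(colour = "red", linewidth = 1) +
    ggplot2::annotate("point", x = object$center[1], y = object$center[2]) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (au)", y = "y (au)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
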