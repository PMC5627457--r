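#' Plot binned investigation time
#'
#' For a single session: the per-bin investigation time toward each
#' stimulus. For a group: the mean curve with an SEM ribbon per stimulus.
#'
#' @param x a `session_summary` or `group_summary`.
#' @return a ggplot.
#' @export
plot_binned_time <- function(x) {
  if (inherits(x, "session_summary")) {
    df <- x$binned
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_start_s,
                                       y = .data$time_s,
                                       colour = .data$stimulus)) +
        ggplot2::geom_line() +
        ggplot2::geom_point(size = 1) +
        ggplot2::labs(x = "Time (s)", y = "Investigation time per bin (s)",
                      colour = NULL, title = x$label) +
        ggplot2::theme_minimal()
    )
  }
  stopifnot(inherits(x, "group_summary"))
  df <- x$binned[x$binned$metric == "binned_time_s", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_start_s, y = .data$mean,
                                   colour = .data$stimulus,
                                   fill = .data$stimulus)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Investigation time per bin (s)",
                  colour = NULL, fill = NULL,
                  title = sprintf("Group mean +/- SEM (n = %d)", x$n)) +
    ggplot2::theme_minimal()
}

#' Raster of investigation bouts
#'
#' Each bout drawn as a horizontal bar at its stimulus, coloured by
#' stimulus, over session time — the classic bout raster.
#'
#' @param bouts bout tibble from [extract_bouts()], or a
#'   `session_summary`.
#' @return a ggplot.
#' @export
plot_bout_raster <- function(bouts) {
  if (inherits(bouts, "session_summary")) bouts <- bouts$bouts
  ggplot2::ggplot(bouts) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start_s, xend = .data$end_s,
                   y = .data$stimulus, yend = .data$stimulus,
                   colour = .data$stimulus),
      linewidth = 6
    ) +
    ggplot2::labs(x = "Time (s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Per-bin transition counts
#'
#' @param x a `session_summary` or `group_summary`.
#' @return a ggplot.
#' @export
plot_transitions <- function(x) {
  if (inherits(x, "session_summary")) {
    df <- x$transitions_per_bin
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_start_s, y = .data$n)) +
        ggplot2::geom_col(fill = "grey40") +
        ggplot2::labs(x = "Time (s)", y = "Transitions per bin",
                      title = x$label) +
        ggplot2::theme_minimal()
    )
  }
  stopifnot(inherits(x, "group_summary"))
  df <- x$binned[x$binned$metric == "transitions_per_bin", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_start_s, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line(colour = "red") +
    ggplot2::labs(x = "Time (s)", y = "Transitions per bin",
                  title = sprintf("Group mean +/- SEM (n = %d)", x$n)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_binned_time
#' @param object a `session_summary`.
#' @param ... unused.
#' @export
autoplot.session_summary <- function(object, ...) plot_binned_time(object)

#' @rdname plot_binned_time
#' @export
autoplot.group_summary <- function(object, ...) plot_binned_time(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
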