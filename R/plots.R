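# ggplot2 views of the manifold, trajectories and training history.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a projected manifold coloured by stage
#'
#' @param projected Tibble with `proj1`, `proj2` and optionally a stage
#'   column.
#' @param colour Name of the column to colour by (default `stage_true` if
#'   present, else none).
#' @return A ggplot.
#' @export
plot_manifold <- function(projected, colour = NULL) {
  if (is.null(colour)) {
    colour <- intersect(c("stage_true", "stage_raw", "stage"),
                        names(projected))[1]
  }
  p <- ggplot2::ggplot(projected, ggplot2::aes(x = .data$proj1, y = .data$proj2))
  if (!is.na(colour) && !is.null(colour)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                                 size = 0.6, alpha = 0.7)
  } else {
    p <- p + ggplot2::geom_point(size = 0.6, alpha = 0.7)
  }
  p + ggplot2::labs(x = "projection axis 1", y = "projection axis 2") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.trajectory_curve <- function(object, events = NULL, ...) {
  df <- tibble::tibble(time_min = object$time_min, raw = object$raw,
                       smoothed = object$smoothed)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$raw), size = 0.5,
                        colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "steelblue") +
    ggplot2::labs(x = "time (min)", y = "projected coordinate") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events$events) > 0) {
    ev <- dplyr::mutate(events$events,
                        time_min = object$time_min[.data$frame],
                        value = object$smoothed[.data$frame])
    p <- p +
      ggplot2::geom_point(data = ev,
                          ggplot2::aes(y = .data$value, shape = .data$type),
                          colour = "firebrick", size = 2.5) +
      ggplot2::geom_text(data = ev,
                         ggplot2::aes(y = .data$value, label = .data$stage),
                         vjust = -1, size = 3)
  }
  p
}

#' @export
autoplot.manifold_model <- function(object, ...) {
  lg <- object$training_log
  if (is.null(lg)) stop("model has no training log")
  long <- tidyr::pivot_longer(lg, cols = c("pixel", "feature", "kl",
                                           "adv_gen", "adv_disc", "tcc"),
                              names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$global_epoch, y = .data$value,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~stage, scales = "free_x") +
    ggplot2::labs(x = "epoch", y = "loss term") +
    ggplot2::theme_minimal()
}
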