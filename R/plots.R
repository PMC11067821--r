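#' Plot a fixation trial over its stimulus
#'
#' Scanpath view: word AOI boxes and line centers in the background, the
#' fixation path on top, points sized by duration (when available) and
#' coloured by true line label (when available). The y axis is reversed to
#' match screen coordinates.
#'
#' @param fixations Fixation tibble.
#' @param stimulus Optional `gw_stimulus` drawn behind the scanpath.
#' @return A ggplot object.
#' @export
plot_trial <- function(fixations, stimulus = NULL) {
  fx <- as_fixations(fixations)
  p <- ggplot2::ggplot()
  if (!is.null(stimulus)) {
    p <- p +
      ggplot2::geom_rect(
        data = stimulus$words,
        ggplot2::aes(xmin = .data$x_min, xmax = .data$x_max,
                     ymin = .data$y_min, ymax = .data$y_max),
        fill = "grey92", colour = "grey75", linewidth = 0.2
      ) +
      ggplot2::geom_hline(yintercept = stimulus$lines$y_center,
                          colour = "grey80", linetype = "dotted")
  }
  p <- p + ggplot2::geom_path(data = fx, ggplot2::aes(.data$x, .data$y),
                              colour = "steelblue", alpha = 0.5)
  aes_pt <- if ("true_line" %in% names(fx)) {
    ggplot2::aes(.data$x, .data$y, colour = factor(.data$true_line))
  } else {
    ggplot2::aes(.data$x, .data$y)
  }
  size <- if ("duration" %in% names(fx)) fx$duration / 100 else 2
  p +
    ggplot2::geom_point(data = fx, aes_pt, size = size, alpha = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "line") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_trial Scanpath of a correction result: original positions
#'   joined to their snapped line centers.
#' @param object,... `autoplot` arguments (`object` is the result; pass
#'   `stimulus` through `...` for the background geometry).
#' @method autoplot gw_correction
#' @export
autoplot.gw_correction <- function(object, ..., stimulus = NULL) {
  p <- plot_trial(tidy.gw_correction(object), stimulus)
  p + ggplot2::geom_segment(
    data = tidy.gw_correction(object),
    ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x,
                 yend = .data$y_corrected),
    colour = "firebrick", alpha = 0.4, linetype = "dashed"
  ) +
    ggplot2::ggtitle(sprintf("correction: %s", attr(object, "algorithm")))
}

#' Accuracy curves of a benchmark report
#'
#' Mean line-assignment accuracy against distortion magnitude, one line per
#' algorithm, faceted by distortion kind.
#'
#' @param object A `gw_report`.
#' @param ... Unused.
#' @method autoplot gw_report
#' @export
autoplot.gw_report <- function(object, ...) {
  ggplot2::ggplot(tidy.gw_report(object),
                  ggplot2::aes(.data$magnitude, .data$mean_accuracy,
                               colour = .data$algorithm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$kind), scales = "free_x") +
    ggplot2::labs(x = "distortion magnitude", y = "mean accuracy (%)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' False-positive-rate curves of the regression detector
#'
#' @param object A `gw_fp_study`.
#' @param ... Unused.
#' @method autoplot gw_fp_study
#' @export
autoplot.gw_fp_study <- function(object, ...) {
  df <- object
  class(df) <- class(tibble::tibble())
  ggplot2::ggplot(df, ggplot2::aes(.data$magnitude, .data$fp_rate,
                                   colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$kind), scales = "free_x") +
    ggplot2::labs(x = "distortion magnitude", y = "false-positive rate") +
    ggplot2::theme_minimal()
}
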