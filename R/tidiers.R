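#' Tidy a correction result
#'
#' Returns the per-fixation result as a plain tibble (one row per fixation,
#' with `line` and `y_corrected`).
#'
#' @param x A `gw_correction`.
#' @param ... Unused.
#' @method tidy gw_correction
#' @export
tidy.gw_correction <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  attr(out, "algorithm") <- NULL
  attr(out, "fit") <- NULL
  attr(out, "mask") <- NULL
  out
}

#' One-row summary of a correction result
#'
#' Reports the algorithm tag, trial size, number of distinct lines used and —
#' for the model-fitting correctors — the fitted drift parameters.
#'
#' @inheritParams tidy.gw_correction
#' @method glance gw_correction
#' @export
glance.gw_correction <- function(x, ...) {
  fit <- attr(x, "fit")
  out <- tibble::tibble(
    algorithm = attr(x, "algorithm"),
    n_fixations = nrow(x),
    n_lines_used = dplyr::n_distinct(x$line)
  )
  if (!is.null(fit)) out <- dplyr::bind_cols(out, tibble::as_tibble(fit))
  out
}

#' @export
print.gw_correction <- function(x, ...) {
  cat(sprintf("<gw_correction: %s> %d fixations on %d lines\n",
              attr(x, "algorithm"), nrow(x), dplyr::n_distinct(x$line)))
  NextMethod()
}

#' Tidy confusion metrics into metric/value pairs
#'
#' @param x A `gw_confusion` from [confusion_metrics()].
#' @param ... Unused.
#' @method tidy gw_confusion
#' @export
tidy.gw_confusion <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(unclass(x)),
                      dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.gw_confusion
#' @method glance gw_confusion
#' @export
glance.gw_confusion <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}

#' Tidy / summarise a benchmark report
#'
#' `tidy()` returns the per-cell tibble; `glance()` collapses to one row per
#' algorithm with the grand mean accuracy over all simulated cells.
#'
#' @param x A `gw_report` from [run_distortion_suite()].
#' @param ... Unused.
#' @method tidy gw_report
#' @export
tidy.gw_report <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidy.gw_report
#' @method glance gw_report
#' @export
glance.gw_report <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(tidy.gw_report(x), .data$algorithm),
                   mean_accuracy = mean(.data$mean_accuracy),
                   n_cells = dplyr::n(), .groups = "drop")
}
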