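#' Flag regressive fixations in a trial
#'
#' Scans the fixation sequence in order, maintaining an anchor at the most
#' recent non-regressive fixation `(last_x, last_y)`. Relative to that anchor,
#' a fixation starts or continues a regression episode when either condition
#' holds:
#'
#' * within-line: `x < last_x - line_height / 2` and
#'   `y <= last_y + line_height / 2` (a leftward jump that stays near the
#'   anchor's line band), or
#' * between-line: `y < last_y - line_height / 2` (an upward jump of more
#'   than half a line).
#'
#' The anchor is frozen for the whole episode, so every fixation above the
#' anchor-defined boundary belongs to the episode regardless of its immediate
#' predecessor. The first fixation that fails both conditions ends the
#' episode, is itself non-regressive, and becomes the new anchor. The first
#' fixation of a trial is never regressive. Boundary cases follow the strict
#' and non-strict inequalities exactly as written above. Because both
#' conditions are relative to fixation positions (not the text), detection
#' works even when the whole trial is displaced; with variable line spacing
#' pass the mean line height.
#'
#' @param fixations Fixation tibble.
#' @param line_height Line height in px (> 0); use [mean_line_height()] for
#'   stimuli with variable spacing.
#' @return A `gw_mask` tibble with columns `seq`, `regressive` (logical) and
#'   `episode` (0-based episode id, `NA` outside episodes), plus an
#'   `episodes` attribute: a tibble of half-open `[start, end)` seq intervals.
#' @export
flag_regressive_fixations <- function(fixations, line_height) {
  fx <- as_fixations(fixations)
  if (!is.numeric(line_height) || line_height <= 0) {
    abort("'line_height' must be a positive number")
  }
  h2 <- line_height / 2
  n <- nrow(fx)
  flags <- logical(n)
  ax <- fx$x[1]
  ay <- fx$y[1]
  if (n > 1) {
    for (i in 2:n) {
      eq1 <- fx$x[i] < ax - h2 && fx$y[i] <= ay + h2
      eq2 <- fx$y[i] < ay - h2
      if (eq1 || eq2) {
        flags[i] <- TRUE
      } else {
        ax <- fx$x[i]
        ay <- fx$y[i]
      }
    }
  }
  mask_from_flags(fx$seq, flags)
}

mask_from_flags <- function(seq, flags) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  episodes <- tibble::tibble(
    start = seq[starts[keep]],
    end = seq[ends[keep]] + 1L
  )
  episode <- rep(NA_integer_, length(flags))
  for (e in seq_along(keep)) {
    episode[starts[keep[e]]:ends[keep[e]]] <- e - 1L
  }
  out <- tibble::tibble(seq = seq, regressive = flags, episode = episode)
  class(out) <- c("gw_mask", class(out))
  attr(out, "episodes") <- episodes
  out
}

#' Classify a trial as containing a regression or not
#'
#' `TRUE` when [flag_regressive_fixations()] marks any fixation regressive.
#'
#' @inheritParams flag_regressive_fixations
#' @return Logical scalar.
#' @export
classify_trial <- function(fixations, line_height) {
  any(flag_regressive_fixations(fixations, line_height)$regressive)
}

#' Split a trial into non-regressive and regressive parts
#'
#' Partitions the fixations by a regression mask, preserving the original
#' `seq` labels and relative order inside each part, so [merge_trial()] can
#' reassemble the original sequence exactly.
#'
#' @param fixations Fixation tibble.
#' @param mask A `gw_mask` from [flag_regressive_fixations()], or a logical
#'   vector of the same length.
#' @return A list with tibbles `non_regressive` and `regressive`.
#' @export
split_trial <- function(fixations, mask) {
  fx <- as_fixations(fixations)
  flags <- if (is.data.frame(mask)) mask$regressive else mask
  if (length(flags) != nrow(fx)) {
    abort("mask length does not match the number of fixations")
  }
  list(
    non_regressive = fx[!flags, , drop = FALSE],
    regressive = fx[flags, , drop = FALSE]
  )
}

#' Merge split fixation parts back into one trial
#'
#' Interleaves the two parts by their original `seq` labels, which must be
#' disjoint and jointly contiguous (0..n-1).
#'
#' @param non_regressive,regressive Fixation tibbles produced by
#'   [split_trial()] (either may be empty).
#' @return The merged fixation tibble in original sequence order.
#' @export
merge_trial <- function(non_regressive, regressive) {
  merged <- dplyr::bind_rows(
    tibble::as_tibble(non_regressive),
    tibble::as_tibble(regressive)
  )
  if (!"seq" %in% names(merged)) {
    abort("both parts must carry their original 'seq' labels")
  }
  if (nrow(merged) == 0) abort("both parts are empty", class = "gw_empty_trial")
  if (anyDuplicated(merged$seq) ||
      !identical(sort(merged$seq), seq_len(nrow(merged)) - 1L)) {
    abort("seq labels must be disjoint and jointly contiguous (0..n-1)")
  }
  dplyr::arrange(merged, .data$seq)
}
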