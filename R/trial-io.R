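#' Coerce a data frame to a fixation sequence
#'
#' Fixation sequences are plain tibbles with one row per fixation, ordered by
#' occurrence. Required columns: `x`, `y` (px, y-down screen coordinates).
#' Optional: `duration` (ms, non-negative; carried through but never used by
#' any corrector), `true_line` (0-based ground-truth line index for synthetic
#' or manually corrected data) and `seq` (0-based position in the trial; added
#' from row order when absent).
#'
#' @param fixations Data frame of fixations.
#' @param require_nonempty Error on zero rows (the correctors require at least
#'   one fixation).
#' @return A tibble with a valid, contiguous 0-based `seq` column.
#' @export
as_fixations <- function(fixations, require_nonempty = TRUE) {
  fixations <- tibble::as_tibble(fixations)
  if (require_nonempty && nrow(fixations) == 0) {
    abort("fixation sequence is empty", class = "gw_empty_trial")
  }
  for (f in c("x", "y")) {
    if (!f %in% names(fixations)) {
      abort(sprintf("fixations are missing required column '%s'", f),
            class = "gw_format_error")
    }
    if (!is.numeric(fixations[[f]])) {
      abort(sprintf("fixation column '%s' must be numeric", f),
            class = "gw_format_error")
    }
  }
  if ("duration" %in% names(fixations) && any(fixations$duration < 0, na.rm = TRUE)) {
    abort("fixation durations must be non-negative", class = "gw_format_error")
  }
  if (!"seq" %in% names(fixations)) {
    fixations$seq <- seq_len(nrow(fixations)) - 1L
  } else {
    fixations$seq <- as.integer(fixations$seq)
    if (nrow(fixations) > 0 &&
        !identical(sort(fixations$seq), seq_len(nrow(fixations)) - 1L)) {
      abort("fixation 'seq' must be the contiguous 0-based positions 0..n-1",
            class = "gw_format_error")
    }
    fixations <- dplyr::arrange(fixations, .data$seq)
  }
  fixations
}

#' Read a fixation trial from CSV or JSON
#'
#' CSV trials have a header row and columns `x,y,duration[,line]`; JSON trials
#' are `{"fixations":[{"x":..,"y":..,"duration":..,"line":..}]}`. The optional
#' `line` field is the ground-truth line label and is returned as `true_line`.
#'
#' @param path File to read.
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @return A fixation tibble (see [as_fixations()]).
#' @examples
#' path <- system.file("extdata", "example_trial.csv", package = "gazewarp")
#' head(load_trial(path))
#' @export
load_trial <- function(path, format = c("csv", "json")) {
  if (!file.exists(path)) abort(sprintf("trial file does not exist: %s", path))
  format <- if (missing(format)) infer_format_trial(path) else match.arg(format)
  if (format == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    fx <- raw$fixations
    if (is.null(fx) || NROW(fx) == 0) {
      abort("trial file contains no fixations", class = "gw_empty_trial")
    }
    fx <- tibble::as_tibble(fx)
  } else {
    if (file.size(path) == 0) {
      abort("trial file is empty", class = "gw_empty_trial")
    }
    fx <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
    if (nrow(fx) == 0) {
      abort("trial file contains no fixations", class = "gw_empty_trial")
    }
    for (f in c("x", "y", "duration")) {
      if (!f %in% names(fx)) {
        abort(sprintf("trial CSV is missing required column '%s'", f),
              class = "gw_format_error")
      }
      parsed <- suppressWarnings(as.numeric(fx[[f]]))
      bad <- which(is.na(parsed) & !is.na(fx[[f]]))
      if (length(bad) > 0) {
        abort(sprintf("non-numeric value '%s' in column '%s' at row %d",
                      fx[[f]][bad[1]], f, bad[1]),
              class = "gw_format_error")
      }
      fx[[f]] <- parsed
    }
    if ("line" %in% names(fx)) fx$line <- suppressWarnings(as.integer(fx$line))
  }
  for (f in c("x", "y", "duration")) {
    if (!f %in% names(fx)) {
      abort(sprintf("trial is missing required column '%s'", f),
            class = "gw_format_error")
    }
  }
  if ("line" %in% names(fx)) {
    fx <- dplyr::rename(fx, true_line = "line")
    fx$true_line <- as.integer(fx$true_line)
  }
  as_fixations(fx)
}

#' Write a fixation trial to CSV or JSON
#'
#' The JSON round trip is bit-exact; the CSV round trip preserves coordinates
#' to full double precision as written by `readr`.
#'
#' @param fixations Fixation tibble.
#' @param path Output file.
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @return `path`, invisibly.
#' @export
save_trial <- function(fixations, path, format = c("csv", "json")) {
  fixations <- as_fixations(fixations)
  format <- if (missing(format)) infer_format_trial(path) else match.arg(format)
  out <- fixations[, intersect(c("x", "y", "duration", "true_line"),
                               names(fixations)), drop = FALSE]
  if ("true_line" %in% names(out)) out <- dplyr::rename(out, line = "true_line")
  if (format == "json") {
    # I(17) significant digits: doubles survive the round trip bit-exactly
    jsonlite::write_json(list(fixations = out), path,
                         dataframe = "rows", auto_unbox = TRUE, digits = I(17))
  } else {
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}

infer_format_trial <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json", "csv")) ext else "csv"
}
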