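#' Construct a stimulus from line and word tables
#'
#' A stimulus is the static text geometry every corrector consults: the set of
#' text lines (vertical centers and heights, in screen pixels with the origin
#' at the top-left and y increasing downward) and the word areas-of-interest
#' (AOIs) that surround each token, held in reading order (top-to-bottom, then
#' left-to-right).
#'
#' @param lines Data frame with columns `index` (0-based integer), `y_center`
#'   (px) and `height` (px, > 0). Rows are sorted by `y_center`; if the given
#'   order disagrees, they are re-sorted with a notice.
#' @param words Data frame with columns `token`, `line_index`, `x_min`,
#'   `x_max`, `y_min`, `y_max` and optionally `x_center`, `y_center`, `ovp_x`
#'   (all px). Missing centers are derived from the bounds; a missing `ovp_x`
#'   (optimal viewing position, slightly left of the word center for
#'   left-to-right scripts) defaults to `x_min + 0.4 * (x_max - x_min)`.
#'   Words are re-sorted into reading order.
#' @return An object of class `gw_stimulus`: a list with tibbles `lines` and
#'   `words`.
#' @seealso [stimulus_bubble_sort()] for the bundled source-code fixture,
#'   [load_stimulus()] for file input.
#' @export
new_stimulus <- function(lines, words) {
  lines <- tibble::as_tibble(lines)
  words <- tibble::as_tibble(words)

  for (f in c("index", "y_center", "height")) {
    if (!f %in% names(lines)) {
      abort(sprintf("stimulus lines are missing required field '%s'", f),
            class = "gw_format_error")
    }
  }
  for (f in c("token", "line_index", "x_min", "x_max", "y_min", "y_max")) {
    if (!f %in% names(words)) {
      abort(sprintf("stimulus words are missing required field '%s'", f),
            class = "gw_format_error")
    }
  }
  if (nrow(lines) == 0) {
    abort("a stimulus needs at least one line", class = "gw_format_error")
  }
  if (any(lines$height <= 0)) {
    abort("line heights must be positive", class = "gw_format_error")
  }
  if (is.unsorted(lines$y_center, strictly = FALSE)) {
    inform("stimulus lines were not sorted by y_center; re-sorting")
    lines <- dplyr::arrange(lines, .data$y_center)
  }
  lines$index <- as.integer(lines$index)

  if (nrow(words) > 0) {
    if (!all(words$line_index %in% lines$index)) {
      bad <- setdiff(unique(words$line_index), lines$index)
      abort(sprintf("word line_index %s does not refer to an existing line",
                    paste(bad, collapse = ", ")),
            class = "gw_format_error")
    }
    if (any(words$x_min >= words$x_max) || any(words$y_min >= words$y_max)) {
      abort("word AOI bounds must satisfy x_min < x_max and y_min < y_max",
            class = "gw_format_error")
    }
    if (!"x_center" %in% names(words)) {
      words$x_center <- (words$x_min + words$x_max) / 2
    }
    if (!"y_center" %in% names(words)) {
      words$y_center <- (words$y_min + words$y_max) / 2
    }
    if (!"ovp_x" %in% names(words)) {
      words$ovp_x <- words$x_min + 0.4 * (words$x_max - words$x_min)
    }
    if (any(words$x_center < words$x_min | words$x_center > words$x_max)) {
      abort("word x_center must lie within its bounds", class = "gw_format_error")
    }
    words$line_index <- as.integer(words$line_index)
    words <- dplyr::arrange(words, .data$line_index, .data$x_center)
  }

  structure(list(lines = lines, words = words), class = "gw_stimulus")
}

#' @export
print.gw_stimulus <- function(x, ...) {
  cat(sprintf("<gw_stimulus> %d lines, %d words, mean line height %.1f px\n",
              nrow(x$lines), nrow(x$words), mean_line_height(x)))
  invisible(x)
}

#' Load a stimulus description from file
#'
#' JSON stimuli follow the schema
#' `{"lines":[{"index":..,"y_center":..,"height":..}],`
#' `"words":[{"token":..,"line_index":..,"x_min":..,"x_max":..,"y_min":..,"y_max":..,"ovp_x":..}]}`.
#' CSV stimuli are a single table with a `record` column holding `"line"` or
#' `"word"` and the union of the line and word columns, unused cells empty.
#'
#' @param path Path to the stimulus file.
#' @param format `"json"` or `"csv"`; defaults to the file extension.
#' @return A [new_stimulus()] object.
#' @examples
#' path <- system.file("extdata", "bubble_sort_stimulus.json",
#'                     package = "gazewarp")
#' load_stimulus(path)
#' @export
load_stimulus <- function(path, format = c("json", "csv")) {
  if (!file.exists(path)) {
    abort(sprintf("stimulus file does not exist: %s", path))
  }
  format <- if (missing(format)) infer_format(path) else match.arg(format)
  if (format == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (f in c("lines", "words")) {
      if (is.null(raw[[f]])) {
        abort(sprintf("stimulus file is missing required field '%s'", f),
              class = "gw_format_error")
      }
    }
    new_stimulus(raw$lines, raw$words)
  } else {
    tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!"record" %in% names(tab)) {
      abort("stimulus CSV is missing required field 'record'",
            class = "gw_format_error")
    }
    lines <- dplyr::filter(tab, .data$record == "line")
    words <- dplyr::filter(tab, .data$record == "word")
    keep <- function(df, cols) df[, intersect(cols, names(df)), drop = FALSE]
    new_stimulus(
      keep(lines, c("index", "y_center", "height")),
      keep(words, c("token", "line_index", "x_min", "x_max", "y_min", "y_max",
                    "x_center", "y_center", "ovp_x"))
    )
  }
}

#' Mean line height of a stimulus
#'
#' With variable vertical spacing (common in source code) the regression
#' detector and the correctors work with the arithmetic mean of the line
#' heights.
#'
#' @param stimulus A `gw_stimulus`.
#' @return Mean line height in px.
#' @export
mean_line_height <- function(stimulus) {
  stopifnot(inherits(stimulus, "gw_stimulus"))
  if (nrow(stimulus$lines) == 0) abort("stimulus has no lines")
  mean(stimulus$lines$height)
}

#' Nearest text line for vertical positions
#'
#' Maps each y coordinate to the 0-based index of the line whose center is
#' closest. Ties break toward the lower index (top-to-bottom reading
#' priority), so the result is deterministic.
#'
#' @param y Numeric vector of vertical positions (px, y-down).
#' @param stimulus A `gw_stimulus`.
#' @return Integer vector of 0-based line indices, one per element of `y`.
#' @export
nearest_line <- function(y, stimulus) {
  stopifnot(inherits(stimulus, "gw_stimulus"))
  centers <- stimulus$lines$y_center
  if (length(centers) == 0) abort("stimulus has no lines")
  d <- abs(outer(y, centers, "-"))
  idx <- max.col(-d, ties.method = "first")
  stimulus$lines$index[idx]
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json", "csv")) ext else "json"
}

#' Bundled source-code stimulus: a Bubble-Sort Java function
#'
#' Builds the package's reference stimulus: a small Java function that
#' performs bubble sort, laid out on a fixed character grid as a monospace
#' code listing. It contains comments, short tokens (braces, operators,
#' keywords) and trailing closing-brace lines — the features of code stimuli
#' that make fixation-to-line assignment hard, such as heavily skipped short
#' tokens at the bottom of the screen.
#'
#' Each whitespace-delimited token becomes one word AOI; its horizontal bounds
#' come from its character span, its vertical bounds from the line band. The
#' optimal viewing position sits at 40% of the token width, slightly left of
#' center.
#'
#' @param line_height Vertical distance between line centers, px (default 50).
#' @param char_width Width of one character cell, px (default 8).
#' @param x_margin,y_margin Offset of the text block from the screen origin, px.
#' @return A `gw_stimulus` with 14 lines and about 60 word AOIs.
#' @export
stimulus_bubble_sort <- function(line_height = 50, char_width = 8,
                                 x_margin = 50, y_margin = 50) {
  src <- bubble_sort_source()
  n_lines <- length(src)
  lines <- tibble::tibble(
    index = seq_len(n_lines) - 1L,
    y_center = y_margin + (seq_len(n_lines) - 0.5) * line_height,
    height = line_height
  )
  words <- purrr::map_dfr(seq_along(src), function(i) {
    toks <- tokenize_line(src[i])
    if (nrow(toks) == 0) return(NULL)
    tibble::tibble(
      token = toks$token,
      line_index = i - 1L,
      x_min = x_margin + toks$start * char_width,
      x_max = x_margin + toks$end * char_width,
      y_min = lines$y_center[i] - line_height / 2,
      y_max = lines$y_center[i] + line_height / 2
    )
  })
  new_stimulus(lines, words)
}

bubble_sort_source <- function() {
  c(
    "public void bubbleSort(int[] arr) {",
    "  int n = arr.length;",
    "  // repeatedly sweep the array",
    "  for (int i = 0; i < n - 1; i++) {",
    "    // bubble the largest item up",
    "    for (int j = 0; j < n - i - 1; j++) {",
    "      if (arr[j] > arr[j + 1]) {",
    "        int temp = arr[j];",
    "        arr[j] = arr[j + 1];",
    "        arr[j + 1] = temp;",
    "      }",
    "    }",
    "  }",
    "}"
  )
}

# Split one source line into whitespace-delimited tokens with 0-based
# character offsets [start, end).
tokenize_line <- function(line) {
  m <- gregexpr("\\S+", line)[[1]]
  if (m[1] == -1) {
    return(tibble::tibble(token = character(), start = integer(), end = integer()))
  }
  tibble::tibble(
    token = regmatches(line, gregexpr("\\S+", line))[[1]],
    start = as.integer(m) - 1L,
    end = as.integer(m) - 1L + attr(m, "match.length")
  )
}
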