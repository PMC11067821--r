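# Independent reference implementations used as oracles. These are written
# straight from first principles (definitions, exhaustive enumeration) and
# share no code with the package internals they check.

# Minimal evenly spaced stimulus with one word per line cell, for geometry
# unit tests that should not depend on the code fixture.
grid_stimulus <- function(n_lines = 5, words_per_line = 4,
                          line_height = 50, word_width = 60, gap = 20,
                          x0 = 100, y0 = 100) {
  lines <- tibble::tibble(
    index = seq_len(n_lines) - 1L,
    y_center = y0 + (seq_len(n_lines) - 0.5) * line_height,
    height = line_height
  )
  words <- purrr::map_dfr(seq_len(n_lines), function(i) {
    x_min <- x0 + (seq_len(words_per_line) - 1) * (word_width + gap)
    tibble::tibble(
      token = sprintf("word%d%d", i, seq_len(words_per_line)),
      line_index = i - 1L,
      x_min = x_min, x_max = x_min + word_width,
      y_min = lines$y_center[i] - line_height / 2,
      y_max = lines$y_center[i] + line_height / 2
    )
  })
  new_stimulus(lines, words)
}

# One fixation exactly on each word's OVP x / line center y: the clean,
# skip-free, jitter-free reading of a stimulus.
clean_trial <- function(stimulus) {
  generate_trial(stimulus,
                 generation_config(skip_prob_short = 0, ovp_jitter = 0,
                                   y_jitter_sd = 0),
                 seed = 1)
}

# DTW cost by plain recursion over the three admissible steps — the
# definition itself, no tabulation.
bf_dtw_cost <- function(a, b) {
  d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(d[1, 1])
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    d[i, j] + best
  }
  rec(nrow(a), nrow(b))
}

# Regression flags straight from the two printed inequalities, one literal
# pass with a frozen anchor.
bf_regression_flags <- function(x, y, h) {
  n <- length(x)
  flags <- logical(n)
  if (n < 2) return(flags)
  last_x <- x[1]; last_y <- y[1]
  for (i in 2:n) {
    within <- (x[i] < last_x - h / 2) && (y[i] <= last_y + h / 2)
    between <- y[i] < last_y - h / 2
    if (within || between) {
      flags[i] <- TRUE
    } else {
      last_x <- x[i]; last_y <- y[i]
    }
  }
  flags
}

# Chain segmentation as a direct scan: new chain whenever either gap reaches
# its threshold; each chain labelled by exhaustive nearest-line of its mean y.
bf_chain_lines <- function(x, y, centers, xt, yt) {
  n <- length(x)
  id <- integer(n); id[1] <- 1L
  if (n > 1) {
    for (i in 2:n) {
      id[i] <- if (abs(x[i] - x[i - 1]) < xt && abs(y[i] - y[i - 1]) < yt)
        id[i - 1] else id[i - 1] + 1L
    }
  }
  out <- integer(n)
  for (c in unique(id)) {
    my <- mean(y[id == c])
    out[id == c] <- which.min(abs(my - centers)) - 1L
  }
  out
}
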