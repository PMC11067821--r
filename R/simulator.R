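#' Parameters of the synthetic reading-trial generator
#'
#' The generator emulates a reader scanning a code stimulus in reading order
#' with normal reading phenomena: short tokens (braces, operators, keywords
#' of at most `short_word_max_chars` characters) are skipped with probability
#' `skip_prob_short`; each fixated word receives one fixation landing within
#' `ovp_jitter` px (uniform) of the word's optimal viewing position
#' horizontally and with Gaussian vertical jitter of sd `y_jitter_sd` px;
#' fixation durations are Gaussian, truncated below at `duration_min` ms.
#'
#' @param skip_prob_short Skip probability for short words (default 0.75).
#' @param short_word_max_chars Maximum token length counted as short
#'   (default 3).
#' @param ovp_jitter Half-width of the uniform horizontal landing jitter, px
#'   (default 15).
#' @param y_jitter_sd Vertical landing jitter sd, px (default 3).
#' @param duration_mean,duration_sd Fixation duration distribution, ms.
#' @param duration_min Lower truncation for durations, ms (default 50).
#' @return A list of class `gw_generation_config`.
#' @export
generation_config <- function(skip_prob_short = 0.75,
                              short_word_max_chars = 3,
                              ovp_jitter = 15,
                              y_jitter_sd = 3,
                              duration_mean = 200,
                              duration_sd = 50,
                              duration_min = 50) {
  if (skip_prob_short < 0 || skip_prob_short > 1) {
    abort("'skip_prob_short' must be a probability in [0, 1]")
  }
  if (ovp_jitter < 0 || y_jitter_sd < 0) abort("jitters must be non-negative")
  structure(
    list(
      skip_prob_short = skip_prob_short,
      short_word_max_chars = short_word_max_chars,
      ovp_jitter = ovp_jitter,
      y_jitter_sd = y_jitter_sd,
      duration_mean = duration_mean,
      duration_sd = duration_sd,
      duration_min = duration_min
    ),
    class = "gw_generation_config"
  )
}

#' Generate one synthetic reading trial
#'
#' Walks the stimulus words in reading order, skipping short words with the
#' configured probability and emitting one jittered fixation per read word.
#' The ground-truth line of every fixation is recorded in `true_line`, and
#' the 0-based index of the word read in `word` (simulator bookkeeping used
#' by the regression injectors).
#'
#' @param stimulus A `gw_stimulus` with at least one word.
#' @param config A [generation_config()].
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (the suites seed per cell instead).
#' @return A fixation tibble with columns `seq`, `x`, `y`, `duration`,
#'   `true_line`, `word`.
#' @export
generate_trial <- function(stimulus, config = generation_config(), seed = NULL) {
  stopifnot(inherits(stimulus, "gw_stimulus"))
  words <- stimulus$words
  if (nrow(words) == 0) abort("stimulus has no word AOIs to read")
  if (!is.null(seed)) set.seed(seed)

  short <- nchar(words$token) <= config$short_word_max_chars
  read <- !short | runif(nrow(words)) >= config$skip_prob_short
  idx <- which(read)
  if (length(idx) == 0) idx <- 1L # degenerate config: still emit one fixation
  fx <- word_fixations(stimulus, idx, config)
  fx$seq <- seq_len(nrow(fx)) - 1L
  fx[, c("seq", "x", "y", "duration", "true_line", "word")]
}

# One jittered fixation per listed word index (1-based into stimulus$words).
word_fixations <- function(stimulus, idx, config) {
  w <- stimulus$words[idx, ]
  centers <- stimulus$lines$y_center[match(w$line_index, stimulus$lines$index)]
  tibble::tibble(
    x = w$ovp_x + runif(length(idx), -config$ovp_jitter, config$ovp_jitter),
    y = centers + rnorm(length(idx), 0, config$y_jitter_sd),
    duration = pmax(config$duration_min,
                    rnorm(length(idx), config$duration_mean, config$duration_sd)),
    true_line = w$line_index,
    word = idx - 1L
  )
}

#' Drift distortion generators
#'
#' Four generators reproduce the systematic errors seen in reading
#' eye-tracking data; each perturbs only the vertical coordinate and leaves
#' `x`, `duration` and the ground-truth labels untouched:
#'
#' * `distort_noise()`: adds an independent Gaussian draw (mean 0, sd
#'   `magnitude` px) to every fixation.
#' * `distort_slope()`: adds `magnitude * (x - min(x))` px, a displacement
#'   growing with horizontal distance from the leftmost fixation
#'   (`magnitude` in px per px).
#' * `distort_shift()`: adds `magnitude * (y - y_first) / (y_last - y_first)`
#'   px, where `y_first`/`y_last` are the first and last line centers, so the
#'   displacement grows from 0 at the top line to `magnitude` px at the
#'   bottom line; single-line stimuli are unchanged.
#' * `distort_offset()`: adds the constant `magnitude` px to every fixation.
#'
#' Magnitude 0 is the identity for all four. Noise magnitudes are typically
#' kept in \[0, 20\] px (the benchmark grid); larger values are allowed with
#' a notice.
#'
#' @param fixations Fixation tibble.
#' @param magnitude Distortion magnitude (units above), non-negative.
#' @param seed Optional integer seed for `distort_noise()`.
#' @param stimulus A `gw_stimulus` (needed by `distort_shift()` for the line
#'   centers).
#' @return The distorted fixation tibble.
#' @name distortions
NULL

#' @rdname distortions
#' @export
distort_noise <- function(fixations, magnitude, seed = NULL) {
  fx <- as_fixations(fixations)
  check_magnitude(magnitude)
  if (magnitude > 20) inform("noise magnitude above the usual 0-20 px range")
  if (!is.null(seed)) set.seed(seed)
  fx$y <- fx$y + rnorm(nrow(fx), 0, magnitude)
  fx
}

#' @rdname distortions
#' @export
distort_slope <- function(fixations, magnitude) {
  fx <- as_fixations(fixations)
  check_magnitude(magnitude)
  fx$y <- fx$y + magnitude * (fx$x - min(fx$x))
  fx
}

#' @rdname distortions
#' @export
distort_shift <- function(fixations, stimulus, magnitude) {
  fx <- as_fixations(fixations)
  check_magnitude(magnitude)
  centers <- stimulus$lines$y_center
  y_first <- centers[1]
  y_last <- centers[length(centers)]
  if (y_last > y_first) {
    fx$y <- fx$y + magnitude * (fx$y - y_first) / (y_last - y_first)
  }
  fx
}

#' @rdname distortions
#' @export
distort_offset <- function(fixations, magnitude) {
  fx <- as_fixations(fixations)
  check_magnitude(magnitude)
  fx$y <- fx$y + magnitude
  fx
}

check_magnitude <- function(magnitude) {
  if (!is.numeric(magnitude) || length(magnitude) != 1 || magnitude < 0) {
    abort("'magnitude' must be a single non-negative number")
  }
}

#' Inject regression episodes into a synthetic trial
#'
#' Emulates regressive reading: scanning the generated fixations in order,
#' each one launches a regression episode with probability `magnitude`. An
#' episode re-fixates a previously read position: a target word is drawn
#' uniformly from the eligible earlier words — on the same line for
#' `kind = "within"`, on a strictly earlier line for `kind = "between"` — and
#' the episode fixates the target and up to two following words (episode
#' length uniform on 1..3, clipped so the episode stays strictly before the
#' launch word; within-line episodes therefore stay on the launch line).
#' Episode fixations use the same landing-jitter model as [generate_trial()]
#' and carry their own ground-truth `true_line`. Reading then resumes at the
#' next unread word; episodes never nest. Launch points with no eligible
#' earlier word are skipped.
#'
#' @param fixations A trial from [generate_trial()] (needs `word` and
#'   `true_line`).
#' @param stimulus The stimulus the trial was generated from.
#' @param kind `"within"` or `"between"`.
#' @param magnitude Per-fixation episode probability in \[0, 1\].
#' @param config The [generation_config()] for episode fixation jitter.
#' @param seed Optional integer seed.
#' @return The augmented fixation tibble (re-sequenced 0..n-1) with an
#'   `episodes` attribute: a tibble with `launch_seq` (seq of the launching
#'   fixation in the returned trial), `target_word` and `length`.
#' @export
inject_regression <- function(fixations, stimulus, kind = c("within", "between"),
                              magnitude, config = generation_config(),
                              seed = NULL) {
  kind <- match.arg(kind)
  fx <- as_fixations(fixations)
  check_magnitude(magnitude)
  if (magnitude > 1) abort("regression 'magnitude' is a probability (<= 1)")
  if (!"word" %in% names(fx)) {
    abort("trial lacks the 'word' column; generate it with generate_trial()")
  }
  if (!is.null(seed)) set.seed(seed)

  launch <- runif(nrow(fx)) < magnitude
  build_episodes(fx, stimulus, kind, which(launch), config)
}

#' Inject exactly one regression episode
#'
#' Used by the classifier-validation study: picks one launch fixation
#' uniformly among those with at least one eligible earlier word and inserts
#' a single episode there, under the same episode model as
#' [inject_regression()].
#'
#' @inheritParams inject_regression
#' @return The augmented trial; errors if no fixation is eligible.
#' @export
inject_one_regression <- function(fixations, stimulus,
                                  kind = c("within", "between"),
                                  config = generation_config(), seed = NULL) {
  kind <- match.arg(kind)
  fx <- as_fixations(fixations)
  if (!is.null(seed)) set.seed(seed)
  eligible <- which(vapply(seq_len(nrow(fx)), function(k) {
    length(eligible_targets(fx, stimulus, kind, k)) > 0
  }, logical(1)))
  if (length(eligible) == 0) {
    abort(sprintf("no fixation can launch a '%s' regression on this trial", kind))
  }
  k <- eligible[sample.int(length(eligible), 1)]
  build_episodes(fx, stimulus, kind, k, config)
}

# 1-based stimulus word indices a regression launched at fixation k may target.
eligible_targets <- function(fx, stimulus, kind, k) {
  launch_word <- fx$word[k] + 1L # 1-based
  launch_line <- fx$true_line[k]
  if (kind == "within") {
    which(stimulus$words$line_index == launch_line &
            seq_len(nrow(stimulus$words)) < launch_word)
  } else {
    which(stimulus$words$line_index < launch_line)
  }
}

build_episodes <- function(fx, stimulus, kind, launch_rows, config) {
  pieces <- list()
  log <- list()
  prev <- 0L
  for (k in launch_rows) {
    targets <- eligible_targets(fx, stimulus, kind, k)
    if (length(targets) == 0) next
    t <- targets[sample.int(length(targets), 1)]
    len <- sample.int(3L, 1)
    ep_words <- t:min(t + len - 1L, fx$word[k]) # stays strictly before launch
    ep <- word_fixations(stimulus, ep_words, config)
    pieces[[length(pieces) + 1]] <- fx[(prev + 1L):k, , drop = FALSE]
    pieces[[length(pieces) + 1]] <- ep
    log[[length(log) + 1]] <- tibble::tibble(
      launch_row = k, target_word = t - 1L, length = length(ep_words)
    )
    prev <- k
  }
  if (prev < nrow(fx)) {
    pieces[[length(pieces) + 1]] <- fx[(prev + 1L):nrow(fx), , drop = FALSE]
  }
  out <- dplyr::bind_rows(pieces)
  out$seq <- seq_len(nrow(out)) - 1L
  out <- out[, c("seq", "x", "y", "duration", "true_line", "word")]
  episodes <- if (length(log) > 0) dplyr::bind_rows(log) else
    tibble::tibble(launch_row = integer(), target_word = integer(),
                   length = integer())
  # translate launch rows (input trial) to seq labels in the output trial
  if (nrow(episodes) > 0) {
    shift <- c(0L, cumsum(vapply(log, function(l) l$length, integer(1))))
    episodes$launch_seq <- episodes$launch_row - 1L +
      shift[seq_len(nrow(episodes))]
    episodes$launch_row <- NULL
  } else {
    episodes$launch_seq <- integer()
    episodes$launch_row <- NULL
  }
  attr(out, "episodes") <- episodes[, c("launch_seq", "target_word", "length")]
  out
}

#' Apply a named distortion or regression generator
#'
#' Dispatcher used by the evaluation suites: `kind` is one of `"noise"`,
#' `"slope"`, `"shift"`, `"offset"`, `"regression_within"`,
#' `"regression_between"`, with the magnitude conventions of the underlying
#' generators ([distortions], [inject_regression()]).
#'
#' @inheritParams inject_regression
#' @param kind Distortion kind.
#' @export
distort <- function(fixations, stimulus, kind, magnitude,
                    config = generation_config(), seed = NULL) {
  kind <- match.arg(kind, GW_DISTORTION_KINDS)
  if (!is.null(seed)) set.seed(seed)
  switch(kind,
    noise = distort_noise(fixations, magnitude),
    slope = distort_slope(fixations, magnitude),
    shift = distort_shift(fixations, stimulus, magnitude),
    offset = distort_offset(fixations, magnitude),
    regression_within = inject_regression(fixations, stimulus, "within",
                                          magnitude, config),
    regression_between = inject_regression(fixations, stimulus, "between",
                                           magnitude, config)
  )
}
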