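#' Line-assignment accuracy
#'
#' Percentage of fixations whose corrected line assignment agrees with the
#' ground truth — the standard agreement metric against a golden set.
#'
#' @param result A `gw_correction`, or an integer vector of assigned lines.
#' @param truth Integer vector of true line indices, same length.
#' @return Accuracy in percent.
#' @export
line_accuracy <- function(result, truth) {
  assigned <- if (is.data.frame(result)) result$line else result
  if (length(assigned) != length(truth)) {
    abort("assignments and truth have different lengths")
  }
  100 * mean(assigned == truth)
}

#' Confusion-matrix metrics for binary classification
#'
#' @param predicted,actual Logical vectors of equal length.
#' @return A one-row tibble of class `gw_confusion` with counts `tp`, `fp`,
#'   `fn`, `tn` and percentages `accuracy`, `precision`, `recall`, `f1`.
#'   Precision and recall are defined as 0 when their denominator is 0; `f1`
#'   is the harmonic mean of precision and recall (0 when both are 0).
#' @export
confusion_metrics <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    abort("'predicted' and 'actual' have different lengths")
  }
  predicted <- as.logical(predicted)
  actual <- as.logical(actual)
  tp <- sum(predicted & actual)
  fp <- sum(predicted & !actual)
  fn <- sum(!predicted & actual)
  tn <- sum(!predicted & !actual)
  precision <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else 100 * tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  out <- tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    accuracy = 100 * (tp + tn) / length(predicted),
    precision = precision, recall = recall, f1 = f1
  )
  class(out) <- c("gw_confusion", class(out))
  out
}

# Deterministic per-cell seed below 2^31 so every suite cell is independently
# reproducible regardless of evaluation order.
cell_seed <- function(master, kind_id, gradation, trial) {
  (((master %% 100003) * 19219 + kind_id * 7919 +
      gradation * 733 + trial) %% 2147483629) + 1
}

#' Validate the regression classifier on synthetic trials
#'
#' Generates `n_trials` synthetic reading trials over the stimulus — half
#' clean, half with exactly one injected regression episode (within- or
#' between-line, chosen uniformly) and no drift distortions — classifies each
#' with [classify_trial()] at the stimulus's mean line height, and reports
#' the resulting confusion metrics.
#'
#' @param stimulus A `gw_stimulus`; defaults to the bundled bubble-sort code.
#' @param n_trials Even number of trials (default 100: 50 clean, 50 with a
#'   regression).
#' @param seed Master seed; trial-level seeds are derived from it.
#' @param config A [generation_config()].
#' @return A `gw_confusion` row with a `details` attribute (per-trial tibble).
#' @export
run_classifier_validation <- function(stimulus = stimulus_bubble_sort(),
                                      n_trials = 100, seed = 1,
                                      config = generation_config()) {
  if (n_trials %% 2 != 0) abort("'n_trials' must be even (50/50 split)")
  h <- mean_line_height(stimulus)
  half <- n_trials / 2
  details <- purrr::map_dfr(seq_len(n_trials), function(i) {
    set.seed(cell_seed(seed, 97L, 0L, i))
    trial <- generate_trial(stimulus, config)
    has_reg <- i > half
    kind <- NA_character_
    if (has_reg) {
      kind <- sample(c("within", "between"), 1)
      trial <- inject_one_regression(trial, stimulus, kind, config)
    }
    predicted <- classify_trial(trial, h)
    tibble::tibble(trial = i, actual = has_reg, kind = kind,
                   predicted = predicted)
  })
  out <- confusion_metrics(details$predicted, details$actual)
  attr(out, "details") <- details
  out
}

#' Magnitude grid for a distortion kind
#'
#' Evenly spaced gradations from 0 to the kind's benchmark maximum: noise
#' 0-20 px sd, slope 0-0.1 px/px, shift 0-1 mean line height (px at the
#' bottom line), offset 0-20 px, regression probability 0-0.5. The offset
#' maximum stays below half a line height: a constant displacement beyond
#' that point moves every fixation nearer the next line's center, which no
#' assignment method (absolute or order-based) can distinguish from a trial
#' actually read one line lower.
#'
#' @param kind Distortion kind (see [distort()]).
#' @param stimulus Stimulus (for the shift maximum).
#' @param gradations Number of grid points (default 11).
#' @return Numeric vector of magnitudes, starting at 0.
#' @export
magnitude_grid <- function(kind, stimulus = stimulus_bubble_sort(),
                           gradations = 11) {
  kind <- match.arg(kind, GW_DISTORTION_KINDS)
  max_mag <- switch(kind,
    noise = 20,
    slope = 0.1,
    shift = mean_line_height(stimulus),
    offset = 20,
    regression_within = 0.5,
    regression_between = 0.5
  )
  seq(0, max_mag, length.out = gradations)
}

#' Run the distortion-correction benchmark suite
#'
#' The core simulation: for every distortion kind and magnitude gradation,
#' generate `n_trials` synthetic trials, distort them, correct each distorted
#' trial with every requested algorithm, and score line-assignment accuracy
#' against the recorded ground truth. One distortion kind is applied at a
#' time.
#'
#' @param stimulus A `gw_stimulus`.
#' @param algorithms Character vector of algorithm tags ([algorithms()]).
#' @param kinds Distortion kinds to simulate.
#' @param n_trials Trials per (kind, gradation) cell.
#' @param gradations Number of magnitude gradations per kind (default 11).
#' @param seed Master seed; cell seeds are derived deterministically.
#' @param gen_config A [generation_config()].
#' @param config A [corrector_config()].
#' @return A `gw_report` tibble with one row per (algorithm, kind, gradation):
#'   columns `algorithm`, `kind`, `gradation` (0-based), `magnitude`,
#'   `mean_accuracy`, `n_trials`.
#' @export
run_distortion_suite <- function(stimulus = stimulus_bubble_sort(),
                                 algorithms = c("warp", "hybrid_attach",
                                                "hybrid_chain", "hybrid_regress",
                                                "hybrid_stretch"),
                                 kinds = GW_DISTORTION_KINDS,
                                 n_trials = 100, gradations = 11, seed = 1,
                                 gen_config = generation_config(),
                                 config = corrector_config()) {
  algorithms <- match.arg(algorithms, GW_ALGORITHMS, several.ok = TRUE)
  kinds <- match.arg(kinds, GW_DISTORTION_KINDS, several.ok = TRUE)
  cells <- list()
  for (kind in kinds) {
    kind_id <- match(kind, GW_DISTORTION_KINDS)
    grid <- magnitude_grid(kind, stimulus, gradations)
    for (g in seq_along(grid)) {
      acc <- matrix(NA_real_, n_trials, length(algorithms),
                    dimnames = list(NULL, algorithms))
      for (tr in seq_len(n_trials)) {
        set.seed(cell_seed(seed, kind_id, g, tr))
        trial <- generate_trial(stimulus, gen_config)
        distorted <- distort(trial, stimulus, kind, grid[g], gen_config)
        for (alg in algorithms) {
          acc[tr, alg] <- tryCatch(
            line_accuracy(correct_fixations(distorted, stimulus, alg, config),
                          distorted$true_line),
            error = function(e) {
              warn(sprintf("%s failed on %s gradation %d trial %d: %s",
                           alg, kind, g - 1L, tr, conditionMessage(e)))
              0
            }
          )
        }
      }
      cells[[length(cells) + 1]] <- tibble::tibble(
        algorithm = algorithms, kind = kind, gradation = g - 1L,
        magnitude = grid[g], mean_accuracy = colMeans(acc), n_trials = n_trials
      )
    }
  }
  out <- dplyr::bind_rows(cells)
  class(out) <- c("gw_report", class(out))
  attr(out, "seed") <- seed
  out
}

#' False-positive rate of regression detection under drift
#'
#' Measures how often regression-free trials are mislabelled as containing a
#' regression once drift distortion is applied: per kind and gradation,
#' `n_trials` clean trials are generated, distorted, and classified with
#' [classify_trial()]; the reported rate is the fraction classified
#' regressive. Translation-like distortions (offset, shift) leave the
#' detector's relative geometry intact; noise and slope increasingly trigger
#' false positives as displacements exceed half a line height.
#'
#' @inheritParams run_distortion_suite
#' @param kinds Drift kinds only (no regression injection).
#' @return A `gw_fp_study` tibble: `kind`, `gradation`, `magnitude`,
#'   `fp_rate` (in \[0, 1\]), `n_trials`.
#' @export
run_fp_rate_study <- function(stimulus = stimulus_bubble_sort(),
                              kinds = c("noise", "slope", "shift", "offset"),
                              n_trials = 100, gradations = 11, seed = 1,
                              gen_config = generation_config()) {
  kinds <- match.arg(kinds, c("noise", "slope", "shift", "offset"),
                     several.ok = TRUE)
  h <- mean_line_height(stimulus)
  rows <- list()
  for (kind in kinds) {
    kind_id <- match(kind, GW_DISTORTION_KINDS)
    grid <- magnitude_grid(kind, stimulus, gradations)
    for (g in seq_along(grid)) {
      fp <- vapply(seq_len(n_trials), function(tr) {
        set.seed(cell_seed(seed, 31L + kind_id, g, tr))
        trial <- generate_trial(stimulus, gen_config)
        distorted <- distort(trial, stimulus, kind, grid[g], gen_config)
        classify_trial(distorted, h)
      }, logical(1))
      rows[[length(rows) + 1]] <- tibble::tibble(
        kind = kind, gradation = g - 1L, magnitude = grid[g],
        fp_rate = mean(fp), n_trials = n_trials
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("gw_fp_study", class(out))
  attr(out, "seed") <- seed
  out
}
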