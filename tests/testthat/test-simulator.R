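test_that("word skipping follows the short-word probability", {
  s <- stimulus_bubble_sort()
  all_read <- generate_trial(s, generation_config(skip_prob_short = 0), seed = 1)
  expect_equal(nrow(all_read), nrow(s$words))
  expect_equal(all_read$word, seq_len(nrow(s$words)) - 1L)

  none_short <- generate_trial(s, generation_config(skip_prob_short = 1), seed = 1)
  toks <- s$words$token[none_short$word + 1]
  expect_true(all(nchar(toks) > 3))
})

test_that("fixations land near the optimal viewing position", {
  s <- stimulus_bubble_sort()
  for (seed in 1:20) {
    tr <- generate_trial(s, seed = seed)
    ovp <- s$words$ovp_x[tr$word + 1]
    expect_true(all(abs(tr$x - ovp) <= 15))
    centers <- s$lines$y_center[tr$true_line + 1]
    expect_true(all(abs(tr$y - centers) < 20)) # ~6 sd
    expect_true(all(tr$duration >= 50))
  }
})

test_that("generation is reproducible from a seed", {
  s <- stimulus_bubble_sort()
  a <- generate_trial(s, seed = 99)
  b <- generate_trial(s, seed = 99)
  expect_identical(a, b)
  r1 <- inject_regression(a, s, "between", 0.4, seed = 5)
  r2 <- inject_regression(a, s, "between", 0.4, seed = 5)
  expect_identical(r1, r2)
  expect_identical(attr(r1, "episodes"), attr(r2, "episodes"))
})

test_that("all generators are the identity at magnitude zero", {
  s <- stimulus_bubble_sort()
  t0 <- generate_trial(s, seed = 3)
  for (kind in c("noise", "slope", "shift", "offset",
                 "regression_within", "regression_between")) {
    out <- distort(t0, s, kind, 0, seed = 1)
    for (col in c("seq", "x", "y", "duration", "true_line", "word")) {
      expect_identical(out[[col]], t0[[col]], info = paste(kind, col))
    }
  }
})

test_that("noise perturbs y only, with the configured spread", {
  s <- stimulus_bubble_sort()
  t0 <- generate_trial(s, seed = 4)
  big <- dplyr::bind_rows(replicate(300, t0, simplify = FALSE))
  big$seq <- seq_len(nrow(big)) - 1L
  noisy <- distort_noise(big, 20, seed = 8)
  expect_identical(noisy$x, big$x)
  expect_identical(noisy$true_line, big$true_line)
  dy <- noisy$y - big$y
  expect_gt(length(dy), 1e4)
  expect_equal(sd(dy), 20, tolerance = 0.05)
  expect_equal(mean(dy), 0, tolerance = 0.5)
})

test_that("slope displacement is proportional to distance from the leftmost fixation", {
  s <- stimulus_bubble_sort()
  t0 <- generate_trial(s, seed = 5)
  sloped <- distort_slope(t0, 0.07)
  dy <- sloped$y - t0$y
  left <- which.min(t0$x)
  expect_equal(dy[left], 0)
  fit <- stats::lm(dy ~ I(t0$x - min(t0$x)))
  expect_equal(unname(stats::coef(fit)[2]), 0.07, tolerance = 1e-10)
  expect_equal(unname(stats::coef(fit)[1]), 0, tolerance = 1e-10)
})

test_that("shift grows monotonically from the first line down", {
  s <- stimulus_bubble_sort()
  t0 <- generate_trial(s, seed = 6)
  shifted <- distort_shift(t0, s, 50)
  dy <- shifted$y - t0$y
  expect_true(all(dy[t0$true_line == 0] < 5))
  # mean displacement non-decreasing in line index
  m <- tapply(dy, t0$true_line, mean)
  expect_true(!is.unsorted(m))
})

test_that("offset is an exact translation", {
  s <- stimulus_bubble_sort()
  t0 <- generate_trial(s, seed = 7)
  off <- distort_offset(t0, 12.5)
  expect_equal(off$y - t0$y, rep(12.5, nrow(t0)))
  expect_equal(diff(off$y), diff(t0$y))
})

test_that("within-line episodes stay on the launch line", {
  s <- stimulus_bubble_sort()
  for (seed in 1:10) {
    t0 <- generate_trial(s, seed = seed)
    tr <- inject_regression(t0, s, "within", 0.5, seed = seed + 100)
    ep <- attr(tr, "episodes")
    for (k in seq_len(nrow(ep))) {
      launch_line <- tr$true_line[tr$seq == ep$launch_seq[k]]
      inserted <- (ep$launch_seq[k] + 1):(ep$launch_seq[k] + ep$length[k])
      expect_true(all(tr$true_line[inserted + 1] == launch_line))
      # the episode target lies strictly before the launch word
      expect_lt(ep$target_word[k], tr$word[tr$seq == ep$launch_seq[k]])
    }
  }
})

test_that("between-line episodes always target a strictly earlier line", {
  s <- stimulus_bubble_sort()
  t0 <- generate_trial(s, seed = 11)
  tr <- inject_regression(t0, s, "between", 1, seed = 12)
  ep <- attr(tr, "episodes")
  expect_gt(nrow(ep), 0)
  launch_lines <- tr$true_line[match(ep$launch_seq, tr$seq)]
  target_lines <- s$words$line_index[ep$target_word + 1]
  expect_true(all(target_lines < launch_lines))
  # every fixation after the first line launches an episode (eligible ones)
  n_eligible <- sum(t0$true_line > 0)
  expect_equal(nrow(ep), n_eligible)
})

test_that("ground-truth labels survive every distortion", {
  s <- stimulus_bubble_sort()
  t0 <- generate_trial(s, seed = 13)
  for (kind in c("noise", "slope", "shift", "offset")) {
    out <- distort(t0, s, kind, magnitude_grid(kind, s)[6], seed = 2)
    expect_identical(out$true_line, t0$true_line, info = kind)
  }
})

test_that("generator configuration is validated", {
  expect_error(generation_config(skip_prob_short = 1.2), "probability")
  expect_error(generation_config(ovp_jitter = -1), "non-negative")
  expect_error(distort_noise(tibble::tibble(x = 1, y = 1), -3), "non-negative")
  expect_error(inject_regression(tibble::tibble(x = 1, y = 1),
                                 stimulus_bubble_sort(), "within", 2),
               "probability")
})
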