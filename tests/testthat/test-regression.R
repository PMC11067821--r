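test_that("left-to-right constant-y reading is never flagged", {
  fx <- tibble::tibble(x = seq(100, 600, 50), y = rep(300, 11))
  mask <- flag_regressive_fixations(fx, 50)
  expect_false(any(mask$regressive))
  expect_equal(nrow(attr(mask, "episodes")), 0)
  expect_false(classify_trial(fx, 50))
})

test_that("the two printed inequalities flag direct substitutions", {
  # anchor (500, 300), candidate (480, 200), line height 50:
  # upward jump 200 < 300 - 25 -> between-line regression
  fx <- tibble::tibble(x = c(500, 480), y = c(300, 200))
  expect_true(flag_regressive_fixations(fx, 50)$regressive[2])
  # within-line: leftward jump past half a line height at similar y
  fx2 <- tibble::tibble(x = c(500, 450), y = c(300, 305))
  expect_true(flag_regressive_fixations(fx2, 50)$regressive[2])
  # boundary: x exactly at last_x - h/2 is NOT a within-line regression
  fx3 <- tibble::tibble(x = c(500, 475), y = c(300, 300))
  expect_false(flag_regressive_fixations(fx3, 50)$regressive[2])
  # boundary: y exactly at last_y - h/2 is NOT a between-line regression
  fx4 <- tibble::tibble(x = c(500, 510), y = c(300, 275))
  expect_false(flag_regressive_fixations(fx4, 50)$regressive[2])
})

test_that("the episode anchor stays frozen until a fixation falls below the line", {
  # 2nd and 3rd fixations are above the anchor's boundary; the 4th returns
  # below it, ends the episode and becomes the new anchor
  fx <- tibble::tibble(
    x = c(500, 480, 520, 540),
    y = c(300, 240, 250, 310)
  )
  mask <- flag_regressive_fixations(fx, 50)
  expect_equal(mask$regressive, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(attr(mask, "episodes")$start, 1L)
  expect_equal(attr(mask, "episodes")$end, 3L)
})

test_that("flags match the straight-from-the-equations re-implementation", {
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(2:60, 1)
    fx <- tibble::tibble(
      x = cumsum(runif(n, -60, 90)) + 300,
      y = cumsum(runif(n, -30, 40)) + 200
    )
    h <- sample(c(30, 50, 64), 1)
    expect_equal(flag_regressive_fixations(fx, h)$regressive,
                 bf_regression_flags(fx$x, fx$y, h))
  }
})

test_that("flags are invariant under constant translation of the trial", {
  s <- stimulus_bubble_sort()
  set.seed(32)
  t0 <- generate_trial(s)
  f0 <- flag_regressive_fixations(t0, 50)$regressive
  expect_identical(flag_regressive_fixations(distort_offset(t0, 37), 50)$regressive, f0)
  shifted <- t0
  shifted$x <- shifted$x + 120
  shifted$y <- shifted$y - 15
  expect_identical(flag_regressive_fixations(shifted, 50)$regressive, f0)
  # shift distortion preserves within-line alignment, hence the mask
  expect_identical(
    flag_regressive_fixations(distort_shift(t0, s, 50), 50)$regressive, f0)
})

test_that("monotone reading with proper return sweeps is all non-regressive", {
  # three lines, x resets left at each return sweep, y drops a full line
  fx <- tibble::tibble(
    x = rep(seq(100, 500, 100), 3),
    y = rep(c(100, 150, 200), each = 5)
  )
  expect_false(classify_trial(fx, 50))
})

test_that("split/merge is the identity for arbitrary masks", {
  set.seed(33)
  for (rep in 1:50) {
    n <- sample(1:40, 1)
    fx <- as_fixations(tibble::tibble(x = runif(n), y = runif(n),
                                      duration = runif(n, 50, 300)))
    flags <- c(FALSE, runif(n - 1) < 0.4)[seq_len(n)]
    parts <- split_trial(fx, flags)
    expect_equal(nrow(parts$non_regressive) + nrow(parts$regressive), n)
    expect_equal(merge_trial(parts$non_regressive, parts$regressive), fx)
  }
})

test_that("split/merge edge cases behave", {
  fx <- as_fixations(tibble::tibble(x = 1:4, y = 1:4))
  parts <- split_trial(fx, rep(FALSE, 4))
  expect_equal(parts$non_regressive, fx)
  expect_equal(nrow(parts$regressive), 0)
  expect_equal(merge_trial(parts$non_regressive, parts$regressive), fx)

  parts2 <- split_trial(fx, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(nrow(parts2$non_regressive), 1)

  expect_error(split_trial(fx, c(TRUE, FALSE)), "length")
  expect_error(merge_trial(fx[1:2, ], fx[2:3, ]), "disjoint")
  singletons <- merge_trial(fx[2, ], fx[1, ])
  expect_equal(singletons$seq, 0:1)
})
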