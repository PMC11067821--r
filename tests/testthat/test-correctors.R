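test_that("attach assigns every fixation to its nearest line", {
  s <- grid_stimulus(5, 3)
  # a fixation exactly on line 1's center stays on line 1; 1 px above line 2
  # still goes to line 2
  fx <- tibble::tibble(x = c(100, 100), y = c(s$lines$y_center[2],
                                              s$lines$y_center[3] - 1))
  res <- correct_attach(fx, s)
  expect_equal(res$line, c(1L, 2L))
  expect_equal(res$y_corrected, s$lines$y_center[c(2, 3)])
  expect_identical(res$x, fx$x)

  set.seed(21)
  rnd <- tibble::tibble(x = runif(500, 0, 700), y = runif(500, 0, 700))
  expected <- vapply(rnd$y, function(y) {
    which.min(abs(y - s$lines$y_center)) - 1L
  }, integer(1))
  expect_equal(correct_attach(rnd, s)$line, expected)
})

test_that("attach is idempotent on its own output", {
  s <- grid_stimulus(4, 3)
  set.seed(22)
  fx <- tibble::tibble(x = runif(40, 0, 600), y = runif(40, 0, 500))
  once <- correct_attach(fx, s)
  again <- correct_attach(
    tibble::tibble(x = once$x, y = once$y_corrected), s)
  expect_equal(again$line, once$line)
  expect_equal(again$y_corrected, once$y_corrected)
})

test_that("chain groups fixations and attaches each chain as a whole", {
  s <- grid_stimulus(4, 3)
  cfg <- corrector_config()
  # 500 px apart in x -> two chains
  fx <- tibble::tibble(x = c(100, 600), y = rep(s$lines$y_center[1], 2))
  expect_equal(length(unique(correct_chain(fx, s, cfg)$line)), 1) # same line though
  # five close fixations, mean y nearest line 0 -> all line 0
  fx2 <- tibble::tibble(x = seq(100, 180, 20),
                        y = s$lines$y_center[1] + c(-10, 5, 0, 8, -3))
  expect_equal(correct_chain(fx2, s, cfg)$line, rep(0L, 5))
  # a straggler: one fixation drags toward line 1 but the chain majority wins
  fx3 <- tibble::tibble(x = c(100, 120, 140), y = c(125, 125, 128))
  expect_equal(length(unique(correct_chain(fx3, s, cfg)$line)), 1)
})

test_that("chain segmentation equals a direct scan re-implementation", {
  s <- grid_stimulus(6, 3)
  cfg <- corrector_config()
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    fx <- tibble::tibble(
      x = cumsum(runif(n, -80, 120)) + 300,
      y = runif(n, 80, 500)
    )
    expect_equal(
      correct_chain(fx, s, cfg)$line,
      bf_chain_lines(fx$x, fx$y, s$lines$y_center,
                     cfg$chain_x_thresh, cfg$chain_y_thresh)
    )
  }
})

test_that("regress reduces to attach on clean data and recovers slope drift", {
  s <- stimulus_bubble_sort()
  t0 <- clean_trial(s)
  expect_equal(correct_regress(t0, s)$line, correct_attach(t0, s)$line)
  expect_equal(correct_regress(t0, s)$line, t0$true_line)

  sloped <- distort_slope(t0, 0.05)
  expect_equal(correct_regress(sloped, s)$line, t0$true_line)
  fit <- attr(correct_regress(sloped, s), "fit")
  expect_equal(fit$slope, 0.05, tolerance = 0.02)
})

test_that("regress on a single-line stimulus assigns line 0 to everything", {
  s <- grid_stimulus(1, 4)
  set.seed(24)
  fx <- tibble::tibble(x = runif(20, 0, 500), y = runif(20, 0, 400))
  expect_equal(correct_regress(fx, s)$line, rep(0L, 20))
})

test_that("stretch finds the identity on clean data and recovers an offset", {
  s <- stimulus_bubble_sort()
  t0 <- clean_trial(s)
  res <- correct_stretch(t0, s)
  fit <- attr(res, "fit")
  expect_equal(fit$scale, 1, tolerance = 0.01)
  expect_equal(fit$offset, 0, tolerance = 2)
  expect_equal(res$line, t0$true_line)

  shifted <- distort_offset(t0, 10)
  res2 <- correct_stretch(shifted, s)
  expect_equal(attr(res2, "fit")$offset, -10, tolerance = 2.5)
  expect_equal(res2$line, t0$true_line)
})

test_that("stretch leaves a single-line trial on that line", {
  s <- grid_stimulus(3, 4)
  fx <- tibble::tibble(x = seq(100, 400, 50),
                       y = rep(s$lines$y_center[2], 7))
  expect_equal(correct_stretch(fx, s)$line, rep(1L, 7))
})

test_that("dtw_align handles the trivial cases", {
  a <- tibble::tibble(x = c(0, 10, 20), y = c(0, 0, 0))
  ali <- dtw_align(a, a)
  expect_equal(ali$cost, 0)
  expect_equal(ali$path$i, 1:3)
  expect_equal(ali$path$j, 1:3)

  one <- dtw_align(tibble::tibble(x = 0, y = 0), tibble::tibble(x = 3, y = 4))
  expect_equal(one$cost, 5)
  expect_equal(nrow(one$path), 1)
  expect_error(dtw_align(a[0, ], a), "empty")
})

test_that("dtw_align equals brute-force enumeration for short sequences", {
  set.seed(25)
  for (n in 1:4) {
    for (m in 1:4) {
      a <- matrix(runif(2 * n, 0, 100), ncol = 2)
      b <- matrix(runif(2 * m, 0, 100), ncol = 2)
      expect_equal(dtw_align(a, b)$cost, bf_dtw_cost(a, b),
                   info = sprintf("n=%d m=%d", n, m))
      # cost is symmetric under swapping the sequences
      expect_equal(dtw_align(a, b)$cost, dtw_align(b, a)$cost)
    }
  }
})

test_that("warp is exact on a clean skip-free trial and monotone in line", {
  s <- stimulus_bubble_sort()
  t0 <- clean_trial(s)
  res <- correct_warp(t0, s)
  expect_equal(res$line, t0$true_line)
  expect_identical(res$x, t0$x)
  expect_true(!is.unsorted(res$line))
})

test_that("warp assignments are essentially invariant to a constant vertical offset", {
  # order-based alignment ignores a uniform translation except where the DTW
  # endpoint constraint redistributes trailing skipped tokens, so the
  # invariance is statistical: agreement stays near-total and accuracy flat
  s <- stimulus_bubble_sort()
  agree <- 0; total <- 0; delta <- numeric(0)
  for (seed in 1:15) {
    t0 <- generate_trial(s, seed = seed)
    base <- correct_warp(t0, s)
    w20 <- correct_warp(distort_offset(t0, 20), s)$line
    agree <- agree + sum(w20 == base$line)
    total <- total + nrow(t0)
    delta <- c(delta,
               line_accuracy(w20, t0$true_line) -
                 line_accuracy(base, t0$true_line))
  }
  expect_gte(agree / total, 0.97)
  expect_gte(mean(delta), -3)
})

test_that("all five base correctors are exact on the clean fixture trial", {
  s <- stimulus_bubble_sort()
  t0 <- clean_trial(s)
  for (alg in c("attach", "chain", "regress", "stretch", "warp")) {
    expect_equal(line_accuracy(correct_fixations(t0, s, alg), t0$true_line),
                 100, info = alg)
  }
})

test_that("correctors reject empty trials and bad configs", {
  s <- grid_stimulus(2, 2)
  empty <- tibble::tibble(x = numeric(), y = numeric())
  expect_error(correct_attach(empty, s), class = "gw_empty_trial")
  expect_error(corrector_config(regress_sd_bounds = c(5, 5)), "ordered pair")
})
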