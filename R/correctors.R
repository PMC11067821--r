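#' Tuning parameters for the base correctors
#'
#' Defaults follow the reference implementations of the published algorithms:
#' chain groups fixations closer than 192 px horizontally and 32 px
#' vertically; regress searches a shared slope in \[-0.1, 0.1\] px/px, a
#' vertical offset in \[-50, 50\] px and a spread in \[1, 20\] px; stretch
#' searches a vertical scale in \[0.9, 1.1\] and an offset in \[-50, 50\] px.
#'
#' @param chain_x_thresh,chain_y_thresh Chain grouping thresholds, px.
#' @param regress_slope_bounds Bounds for the shared regression-line slope
#'   (px vertical per px horizontal).
#' @param regress_offset_bounds Bounds for the shared vertical offset, px.
#' @param regress_sd_bounds Bounds for the Gaussian spread, px.
#' @param stretch_scale_bounds Bounds for the vertical scale factor.
#' @param stretch_offset_bounds Bounds for the vertical offset, px.
#' @return A list of class `gw_corrector_config`.
#' @export
corrector_config <- function(chain_x_thresh = 192,
                             chain_y_thresh = 32,
                             regress_slope_bounds = c(-0.1, 0.1),
                             regress_offset_bounds = c(-50, 50),
                             regress_sd_bounds = c(1, 20),
                             stretch_scale_bounds = c(0.9, 1.1),
                             stretch_offset_bounds = c(-50, 50)) {
  cfg <- list(
    chain_x_thresh = chain_x_thresh,
    chain_y_thresh = chain_y_thresh,
    regress_slope_bounds = regress_slope_bounds,
    regress_offset_bounds = regress_offset_bounds,
    regress_sd_bounds = regress_sd_bounds,
    stretch_scale_bounds = stretch_scale_bounds,
    stretch_offset_bounds = stretch_offset_bounds
  )
  for (b in grep("_bounds$", names(cfg), value = TRUE)) {
    if (length(cfg[[b]]) != 2 || cfg[[b]][1] >= cfg[[b]][2]) {
      abort(sprintf("'%s' must be an ordered pair (low < high)", b))
    }
  }
  structure(cfg, class = "gw_corrector_config")
}

# Shared result assembly: input fixations + 0-based line assignment +
# snapped vertical coordinate. x is never touched by any corrector.
new_correction <- function(fixations, line, stimulus, algorithm, fit = NULL) {
  out <- fixations
  out$line <- as.integer(line)
  out$y_corrected <- stimulus$lines$y_center[match(out$line, stimulus$lines$index)]
  class(out) <- c("gw_correction", class(tibble::tibble()))
  attr(out, "algorithm") <- algorithm
  attr(out, "fit") <- fit
  out
}

#' Correct fixations by attaching each to its closest line
#'
#' The minimalist absolute-position baseline: every fixation is assigned the
#' line whose center is vertically closest, independently of all other
#' fixations.
#'
#' @param fixations Fixation tibble (see [as_fixations()]).
#' @param stimulus A `gw_stimulus`.
#' @return A `gw_correction` tibble: the input plus 0-based `line` and snapped
#'   `y_corrected` columns.
#' @family correctors
#' @export
correct_attach <- function(fixations, stimulus) {
  fx <- as_fixations(fixations)
  new_correction(fx, nearest_line(fx$y, stimulus), stimulus, "attach")
}

#' Correct fixations by chaining neighbours before attaching
#'
#' Consecutive fixations are chained while both the horizontal and vertical
#' gaps stay below the configured thresholds; each chain is then assigned as a
#' whole to the line closest to its mean vertical position. Chaining makes the
#' assignment robust to single stray fixations but remains an
#' absolute-position method.
#'
#' @inheritParams correct_attach
#' @param config A [corrector_config()].
#' @family correctors
#' @export
correct_chain <- function(fixations, stimulus, config = corrector_config()) {
  fx <- as_fixations(fixations)
  n <- nrow(fx)
  breaks <- if (n > 1) {
    abs(diff(fx$x)) >= config$chain_x_thresh | abs(diff(fx$y)) >= config$chain_y_thresh
  } else {
    logical(0)
  }
  chain_id <- cumsum(c(1L, as.integer(breaks)))
  mean_y <- tapply(fx$y, chain_id, mean)
  chain_line <- nearest_line(as.numeric(mean_y), stimulus)
  new_correction(fx, chain_line[chain_id], stimulus, "chain")
}

#' Correct fixations by fitting one regression line per text line
#'
#' Models the recorded trial as the true line pattern seen through a shared
#' linear drift: every text line contributes a candidate line
#' `y = k * x + y_center + o`, and each fixation is scored against its
#' best-fitting candidate under a Gaussian error with spread `sigma`. The
#' slope `k`, offset `o` and spread `sigma` are found by bounded minimisation
#' of the summed negative log-density; fixations are then assigned to their
#' minimum-error line. Because every fixation is free to choose its line, the
#' method is indifferent to regressions.
#'
#' Optimisation is a deterministic multi-start (the corners and center of the
#' bound box) of L-BFGS-B, so results are reproducible. If every start fails,
#' the best point of a coarse grid over the bounds is used and a warning is
#' emitted.
#'
#' @inheritParams correct_chain
#' @family correctors
#' @export
correct_regress <- function(fixations, stimulus, config = corrector_config()) {
  fx <- as_fixations(fixations)
  centers <- stimulus$lines$y_center
  obj <- function(p) {
    e <- abs(outer(fx$y - p[1] * fx$x - p[2], centers, "-"))
    rmin <- e[cbind(seq_len(nrow(e)), max.col(-e, ties.method = "first"))]
    -sum(dnorm(rmin, mean = 0, sd = p[3], log = TRUE))
  }
  lower <- c(config$regress_slope_bounds[1], config$regress_offset_bounds[1],
             config$regress_sd_bounds[1])
  upper <- c(config$regress_slope_bounds[2], config$regress_offset_bounds[2],
             config$regress_sd_bounds[2])
  best <- bounded_multistart(obj, lower, upper)
  e <- abs(outer(fx$y - best$par[1] * fx$x - best$par[2], centers, "-"))
  idx <- max.col(-e, ties.method = "first")
  fit <- list(slope = best$par[1], offset = best$par[2], sd = best$par[3],
              objective = best$value)
  new_correction(fx, stimulus$lines$index[idx], stimulus, "regress", fit = fit)
}

#' Correct fixations by stretching the vertical axis onto the lines
#'
#' Finds a vertical scale `s` and offset `o` (within bounds) minimising the
#' total distance between transformed fixation positions `s * y + o` and
#' their nearest line centers, then assigns each fixation to the nearest line
#' of its transformed position. This is the simplified variant that uses the
#' vertical coordinate only.
#'
#' @inheritParams correct_chain
#' @family correctors
#' @export
correct_stretch <- function(fixations, stimulus, config = corrector_config()) {
  fx <- as_fixations(fixations)
  centers <- stimulus$lines$y_center
  obj <- function(p) {
    ys <- p[1] * fx$y + p[2]
    d <- abs(outer(ys, centers, "-"))
    sum(d[cbind(seq_len(nrow(d)), max.col(-d, ties.method = "first"))])
  }
  lower <- c(config$stretch_scale_bounds[1], config$stretch_offset_bounds[1])
  upper <- c(config$stretch_scale_bounds[2], config$stretch_offset_bounds[2])
  best <- bounded_multistart(obj, lower, upper)
  line <- nearest_line(best$par[1] * fx$y + best$par[2], stimulus)
  fit <- list(scale = best$par[1], offset = best$par[2], objective = best$value)
  new_correction(fx, line, stimulus, "stretch", fit = fit)
}

# Deterministic bounded optimisation, L-BFGS-B from the center of the bound
# box — the behaviour of the published reference correctors, which optimise
# locally from a central start. A local start matters beyond reproducibility:
# with equally spaced lines the objective has a near-degenerate family of
# optima offset by a whole line spacing (every fixation assigned one line
# off), and a global search can land there whenever a noisy outlier beyond
# the top line tips the balance. Corner starts of the bound box are used only
# if the center start fails, and a coarse grid over the bounds is the last
# resort (with a warning).
bounded_multistart <- function(obj, lower, upper) {
  k <- length(lower)
  starts <- rbind(rep(0.5, k), as.matrix(expand.grid(rep(list(c(0, 1)), k))))
  starts <- sweep(sweep(starts, 2, upper - lower, "*"), 2, lower, "+")
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[i, ], obj, method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL
    )
    if (!is.null(res)) {
      res$par <- unname(res$par)
      return(res)
    }
  }
  warn("bounded optimisation failed from every start; using grid fallback")
  grid <- as.matrix(do.call(expand.grid,
                            purrr::map2(lower, upper, ~seq(.x, .y, length.out = 11))))
  vals <- apply(grid, 1, obj)
  list(par = unname(grid[which.min(vals), ]), value = min(vals))
}

#' Dynamic-time-warp alignment of two point sequences
#'
#' Standard dynamic-programming alignment with steps (i-1, j), (i, j-1) and
#' (i-1, j-1), anchored at both endpoints, minimising the summed Euclidean
#' distance between matched points. The returned path is monotone
#' non-decreasing in both indices (1-based, following R convention).
#'
#' @param seq_a,seq_b Data frames or matrices with columns/columns 1:2 giving
#'   x and y coordinates; both must be non-empty.
#' @return A list with `path` (tibble with columns `i`, `j`) and `cost` (px).
#' @export
dtw_align <- function(seq_a, seq_b) {
  a <- as_point_matrix(seq_a, "seq_a")
  b <- as_point_matrix(seq_b, "seq_b")
  n <- nrow(a)
  m <- nrow(b)
  d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    prev <- D[i, ]
    cur <- rep(Inf, m + 1)
    di <- d[i, ]
    for (j in seq_len(m)) {
      best <- prev[j]
      if (prev[j + 1] < best) best <- prev[j + 1]
      if (cur[j] < best) best <- cur[j]
      cur[j + 1] <- di[j] + best
    }
    D[i + 1, ] <- cur
  }
  # backtrack, preferring the diagonal on ties for a deterministic path
  i <- n; j <- m
  path_i <- integer(n + m); path_j <- integer(n + m)
  k <- 1L
  repeat {
    path_i[k] <- i; path_j[k] <- j
    if (i == 1 && j == 1) break
    diag <- D[i, j]; up <- D[i, j + 1]; left <- D[i + 1, j]
    if (diag <= up && diag <= left) { i <- i - 1L; j <- j - 1L }
    else if (up <= left) i <- i - 1L
    else j <- j - 1L
    k <- k + 1L
  }
  list(
    path = tibble::tibble(i = rev(path_i[1:k]), j = rev(path_j[1:k])),
    cost = D[n + 1, m + 1]
  )
}

as_point_matrix <- function(p, what) {
  if (is.data.frame(p)) {
    cols <- if (all(c("x", "y") %in% names(p))) c("x", "y") else 1:2
    p <- as.matrix(p[, cols, drop = FALSE])
  }
  p <- as.matrix(p)
  if (nrow(p) == 0) abort(sprintf("'%s' is empty", what))
  storage.mode(p) <- "double"
  p
}

#' Correct fixations by time-warping them onto the word centers
#'
#' Assumes sequential left-to-right, top-to-bottom reading: the fixation
#' sequence is aligned to the word centers in reading order by [dtw_align()],
#' and each fixation takes the line of the first word center it is matched to
#' (the lowest word index, a deterministic tie-break). Only the vertical
#' coordinate is corrected; the order-based alignment makes the method
#' invariant to drift distortions but fragile under regressions, which violate
#' the sequential-reading assumption.
#'
#' @inheritParams correct_attach
#' @family correctors
#' @export
correct_warp <- function(fixations, stimulus) {
  fx <- as_fixations(fixations)
  if (nrow(stimulus$words) == 0) abort("stimulus has no word AOIs")
  ali <- dtw_align(fx[, c("x", "y")],
                   stimulus$words[, c("x_center", "y_center")])
  first_j <- vapply(seq_len(nrow(fx)), function(i) {
    min(ali$path$j[ali$path$i == i])
  }, integer(1))
  new_correction(fx, stimulus$words$line_index[first_j], stimulus, "warp")
}

#' Run any corrector by name
#'
#' Dispatches to one of the nine algorithms: the five base correctors
#' (`attach`, `chain`, `regress`, `stretch`, `warp`) or the four hybrids
#' (`hybrid_attach`, `hybrid_chain`, `hybrid_regress`, `hybrid_stretch`).
#'
#' @inheritParams correct_chain
#' @param algorithm Algorithm name, one of [algorithms()].
#' @export
correct_fixations <- function(fixations, stimulus, algorithm,
                              config = corrector_config()) {
  algorithm <- match.arg(algorithm, GW_ALGORITHMS)
  switch(algorithm,
    attach = correct_attach(fixations, stimulus),
    chain = correct_chain(fixations, stimulus, config),
    regress = correct_regress(fixations, stimulus, config),
    stretch = correct_stretch(fixations, stimulus, config),
    warp = correct_warp(fixations, stimulus),
    correct_hybrid(fixations, stimulus,
                   secondary = sub("^hybrid_", "", algorithm), config = config)
  )
}

#' Names of the available correction algorithms
#' @return Character vector of the nine algorithm tags.
#' @export
algorithms <- function() GW_ALGORITHMS
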