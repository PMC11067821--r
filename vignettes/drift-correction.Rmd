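---
title: "Correcting vertical drift in reading eye-tracking data with DTW hybrids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting vertical drift in reading eye-tracking data with DTW hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazewarp)
```

## The problem

Eye trackers record fixations with systematic error: the reported gaze
position drifts away from the position the reader actually looked at, through
calibration decay, head movement, and tracker inaccuracy. In reading tasks
the damaging component is vertical — a drift of half a line height moves
every fixation onto the wrong line of text, and any word-level analysis built
on those line assignments is invalid. All methods in this package therefore
target one output: a corrected line assignment (and snapped vertical
coordinate) for every fixation.

Coordinates are screen pixels with the origin at the top-left and y
increasing downward, so "a line lower" means larger y. Line and fixation
indices are 0-based everywhere, including CSV/JSON files.

## The five base correctors

* **attach** assigns each fixation independently to the line with the
  nearest center. Minimal, conservative, and indifferent to fixation order —
  which makes it robust to regressions but helpless against drift larger
  than half a line height.
* **chain** first merges consecutive fixations into chains while the
  horizontal gap stays under 192 px and the vertical gap under 32 px, then
  attaches each chain to the line nearest its mean height. The thresholds
  are the defaults of the published reference implementation; they are wide
  enough to hold a within-line reading sequence together and narrow enough
  that a return sweep always starts a new chain.
* **regress** explains the trial as the true line pattern seen through a
  shared linear distortion: each text line contributes a candidate line
  `y = k*x + y_center + o`, each fixation is scored against its best
  candidate under a Gaussian spread `sigma`, and `(k, o, sigma)` is found by
  bounded maximum likelihood (slope in [-0.1, 0.1] px/px, offset in
  [-50, 50] px, spread in [1, 20] px). Because each fixation picks its line
  freely, regressions cost nothing.
* **stretch** fits a vertical affine map `s*y + o` (scale in [0.9, 1.1],
  offset in [-50, 50] px) minimising the summed distance of transformed
  fixations to their nearest line centers — the simplified variant that uses
  the vertical coordinate only.
* **warp** assumes strictly sequential reading: fixations are aligned to the
  word centers in reading order by dynamic time warping (steps (i-1,j),
  (i,j-1), (i-1,j-1), both endpoints anchored, summed Euclidean cost), and
  each fixation takes the line of the first word center it is matched to.
  Because only the order carries information, warp is nearly indifferent to
  noise, slope, shift and moderate offset — and systematically wrong
  whenever the reader jumps back, which violates its one assumption.

## Regression detection and the hybrid family

Reading source code is dominated by regressions (jumps back to earlier code),
so warp alone is a poor fit there. The hybrid correctors interpose a
regression detector: scanning the trial with an anchor at the most recent
non-regressive fixation `(last_x, last_y)` and line height `h`, a fixation
opens or continues a regression episode when either

* `x < last_x - h/2` and `y <= last_y + h/2` (within-line regression: a
  leftward jump staying near the anchor's line), or
* `y < last_y - h/2` (between-line regression: an upward jump of more than
  half a line),

with the anchor frozen for the duration of the episode; the first fixation
that fails both tests ends the episode, is itself non-regressive, and becomes
the new anchor. The inequalities are implemented exactly as stated, including
the non-strict `<=`; boundary values follow the printed operator. With
variable line spacing the mean line height is used. Because both tests
compare fixations to fixations, not to the text, the detector is invariant
under any constant translation of the trial — which is why pure offset (and,
up to jitter, shift) distortion can never produce a false positive.

A hybrid correction then runs five steps, always all five: flag, split, warp
the sequential remainder (writing warp's snapped y back into those
fixations), merge with the untouched regressive fixations in original order,
and hand the merged sequence to a regression-tolerant secondary corrector
(attach, chain, regress or stretch), whose assignment is the result. Passing
the warped coordinates on (not just the labels) gives the secondary corrector
almost-straight data; on a trial with no detected regression the warped
fixations sit exactly on line centers, so `hybrid_attach` reproduces plain
warp — a property the test suite checks exactly.

```{r example, eval = FALSE}
s <- stimulus_bubble_sort()
trial <- generate_trial(s, seed = 1) |>
  inject_regression(s, "between", magnitude = 0.3, seed = 2)
res <- correct_hybrid(trial, s, secondary = "attach")
line_accuracy(res, trial$true_line)
autoplot(res, stimulus = s)
```

## The synthetic reading simulator

All quantitative claims in this package are established on synthetic trials,
so the generator is first-class, tested code. It emulates a reader scanning
a fixed stimulus — a bubble-sort Java function laid out on a character grid
(8 px per character, 50 px line height), with comments, short operators and
the trailing closing-brace lines typical of code — in reading order:

* words of at most 3 characters ("short words": braces, operators, `for`,
  `int`, ...) are skipped with probability 0.75; longer words are always
  fixated once;
* the landing position is the word's optimal viewing position (40% into the
  word, slightly left of center, as for left-to-right readers) plus uniform
  horizontal jitter of ±15 px; vertical landing jitter is Gaussian with
  sd 3 px. The ±15 px figure is the landing-site spread the simulation is
  designed around; splitting it into a uniform horizontal component and a
  small Gaussian vertical component keeps clean trials free of false
  regression detections (a vertical spread approaching half a line height
  would blur the line structure itself);
* durations are Gaussian (mean 200 ms, sd 50 ms) truncated at 50 ms, carried
  through but never consulted by any corrector.

Distortion generators perturb only y: Gaussian **noise** (sd = magnitude),
**slope** (displacement proportional to horizontal distance from the
leftmost fixation), **shift** (displacement growing from the first to the
last line), and constant **offset**. Regression injectors insert episodes
after a fixation with a given per-fixation probability: a target word is
drawn uniformly from the eligible earlier words (same line for within-line,
any earlier line for between-line), the episode re-fixates the target and up
to two following words (length uniform on 1–3, clipped to stay before the
launch word), with the same landing-jitter model, and reading resumes where
it left off. Episodes never nest, and every fixation carries its true line,
which no distortion touches.

### Benchmark grids

Each distortion kind is benchmarked on an 11-point magnitude grid from zero:
noise 0–20 px, slope 0–0.1 px/px, shift 0–50 px (one line height at the
bottom line), offset 0–20 px, regression probability 0–0.5. The offset
maximum is deliberately below half a line height: a constant displacement
beyond 25 px moves every fixation nearer the *next* line's center, a trial
indistinguishable from one actually read a line lower, which no corrector —
absolute or order-based — can and should undo. Keeping the grid inside that
bound is what makes "every algorithm is invariant to offset" a meaningful,
testable property.

## Numerical choices

* **Bounded fitting (regress, stretch).** A single deterministic L-BFGS-B
  start at the center of the bound box, corners only as error fallback, and
  a coarse grid as last resort. The local start is a substantive choice, not
  a shortcut: with equally spaced lines both objectives have a
  near-degenerate family of optima displaced by a whole line spacing (every
  fixation assigned one line off). On clean data the family ties exactly and
  on noisy data a single outlier beyond the top line can make the displaced
  optimum the *global* one, so a global search occasionally misassigns an
  entire trial. Optimising locally from the center — the behaviour of the
  published reference implementations of these correctors — stays in the
  correct basin.
* **DTW ties.** Backtracking prefers the diagonal step; a fixation matched
  to several words takes the first (lowest word index). Both tie-breaks are
  deterministic.
* **nearest-line ties** break toward the lower line index (top-to-bottom
  reading priority).
* **Degenerate inputs.** Empty trials are rejected with a typed error;
  single-line stimuli make every corrector trivially assign line 0; a
  magnitude of zero turns every generator into the identity (tested
  bit-exactly).
* **Reproducibility.** Every stochastic routine takes a seed; the evaluation
  suites derive a deterministic per-cell seed from the master seed, kind,
  gradation and trial index (kept below 2^31), so any cell can be reproduced
  in isolation and reports are bit-identical across runs.

## Evaluation harness and problem sizes

`line_accuracy()` scores the percentage of fixations assigned their true
line — agreement on labels, not on coordinates. `run_classifier_validation()`
rebuilds the detector study (100 trials, half with exactly one injected
episode of a uniformly chosen kind, no drift) and reports the confusion
metrics, with precision and recall defined as 0 on an empty denominator.
`run_distortion_suite()` runs the full benchmark — kinds × 11 gradations ×
trials × algorithms — and `run_fp_rate_study()` measures how often
regression-free distorted trials are mislabelled. The packaged test suite
runs the corrector benchmarks at 20 trials per cell and the detector studies
at 100, sizes at which every reported contrast is stable across seeds while
the whole suite stays comfortably interactive; `scripts/acceptance.R` uses
50 trials per corrector cell.

## What the synthetic results do and do not show

The simulator reproduces the reading phenomena the correctors are sensitive
to — skipping, landing-site scatter, return sweeps, regressions, and the
four canonical drift patterns — but not others found in real recordings:
no saccade-level samples, no refixations or progressive jumps forward, no
cognitively driven duration structure, one fixed stimulus layout, and
distortions applied one kind at a time. Synthetic accuracy is therefore an
upper bound on real-data behaviour, useful chiefly for the *contrasts* it
exposes (warp vs hybrids under between-line regressions; detector blindness
to translation-like drift).

Two behaviours of the published algorithms reproduce here as intrinsic
properties rather than bugs, and the suites are read accordingly. First,
warp's only systematic error on clean skipped trials sits at the trailing
closing braces: the DTW endpoint constraint must distribute the final
skipped tokens over the last fixations, occasionally labelling the last
fixation with a brace line — the same curly-bracket failure mode that grows
under shift distortion. Second, the regression detector's miss rate is a
direct function of episode geometry: an episode is missed only when it
never jumps further left than half a line height, so with uniformly drawn
targets misses are rare, and detector recall lands above an operating point
derived from generators biased toward short, near-adjacent re-reads.

## Known limitations

* Stimulus geometry must be supplied explicitly (lines with centers and
  heights, word AOIs); there is no extraction from stimulus images.
* The detector is the printed two-inequality heuristic; noise and slope
  distortion inflate its false-positive rate at high magnitudes (the
  suites quantify this), and misdetected fixations are simply handed to the
  regression-tolerant secondary corrector.
* Only the vertical coordinate is corrected; x is never touched, so
  within-word horizontal drift is out of scope.
* The prior-work Cluster, Merge, Segment, Compare and Split algorithms are
  not implemented; the hybrid family uses attach, chain, regress and
  stretch as secondaries.
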