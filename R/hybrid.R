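#' Hybrid correction: warp the sequential part, re-correct the whole
#'
#' The hybrid correctors combine the strengths of the order-based warp
#' corrector (excellent under drift distortions, fragile under between-line
#' regressions) with a regression-tolerant secondary algorithm. The pipeline
#' always runs all five steps:
#'
#' 1. detect regressive fixations with [flag_regressive_fixations()] at the
#'    stimulus's mean line height;
#' 2. split the trial into a sequential non-regressive part and a regressive
#'    part;
#' 3. correct the non-regressive part with [correct_warp()] and write the
#'    snapped vertical coordinates back into those fixations, so later steps
#'    see already-straightened data;
#' 4. merge the warped part with the untouched regressive part in original
#'    sequence order;
#' 5. correct the merged sequence with the secondary algorithm (`attach`,
#'    `chain`, `regress` or `stretch`); its assignments are the result.
#'
#' On trials with no detected regression the warped fixations sit exactly on
#' line centers, so `hybrid_attach` reproduces plain warp's assignments.
#' The secondary corrector is free to move previously warped fixations; the
#' merged sequence is passed to it wholesale.
#'
#' @inheritParams correct_chain
#' @param secondary Regression-tolerant secondary corrector: `"attach"`,
#'   `"chain"`, `"regress"` or `"stretch"`.
#' @return A `gw_correction` tibble tagged `hybrid_<secondary>`.
#' @family correctors
#' @export
correct_hybrid <- function(fixations, stimulus,
                           secondary = c("attach", "chain", "regress", "stretch"),
                           config = corrector_config()) {
  secondary <- match.arg(secondary)
  fx <- as_fixations(fixations)
  mask <- flag_regressive_fixations(fx, mean_line_height(stimulus))
  parts <- split_trial(fx, mask)

  nonreg <- parts$non_regressive
  # renumber for the sub-correction; the first fixation is never regressive,
  # so this part is never empty
  relab <- nonreg
  relab$seq <- seq_len(nrow(relab)) - 1L
  warped <- correct_warp(relab, stimulus)
  nonreg$y <- warped$y_corrected

  merged <- merge_trial(nonreg, parts$regressive)
  res <- switch(secondary,
    attach = correct_attach(merged, stimulus),
    chain = correct_chain(merged, stimulus, config),
    regress = correct_regress(merged, stimulus, config),
    stretch = correct_stretch(merged, stimulus, config)
  )

  out <- new_correction(fx, res$line, stimulus,
                        paste0("hybrid_", secondary), fit = attr(res, "fit"))
  attr(out, "mask") <- mask
  out
}
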