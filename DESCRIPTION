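Package: gazewarp
Title: Hybrid Dynamic-Time-Warp Correction of Vertical Drift in Reading Eye-Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Corrects vertical drift in fixation sequences recorded while reading
    multi-line text or source code. Implements five established fixation-to-line
    correction algorithms (attach, chain, regress, stretch, and dynamic-time-warp
    alignment to word centers) together with a family of hybrid correctors that
    detect regressive fixations, align the sequential remainder by dynamic time
    warping, and re-correct the merged sequence with a regression-tolerant
    algorithm. Ships a synthetic reading-trial simulator (word skipping, optimal
    viewing position jitter, noise/slope/shift/offset drift distortions, and
    within- and between-line regression injection) and an evaluation harness that
    scores line-assignment accuracy and regression-detection quality over
    distortion-magnitude grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
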