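Package: orientrack
Title: Analysis of Head-Fixed Trackball Orienting Behavior, Calcium
    Imaging, and Optogenetic Perturbations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native toolkit for analyzing head-fixed mouse
    visuomotor experiments in which animals report the location of a
    lateralized visual cue by rotating a trackball. Provides a
    deterministic closed-loop task engine (inward and outward
    contingencies, anti-bias cue scheduling, laser-trial scheduling with
    a no-consecutive-trials constraint, spontaneous no-cue sessions),
    behavioral performance metrics and optogenetic laser-effect indices
    with animal-wise permutation tests, a two-photon calcium trace
    pipeline (neuropil correction, density-mode baseline, drift
    detrending, trial tensors, condition statistics, ROC-based visual
    preference scores with shuffle nulls), cross-validated linear
    population decoding of selected actions via cross-session
    pseudotrials, spike-train laser modulation indices, and a body-axis
    pose transform for forepaw position summaries. Synthetic generators
    with known ground truth for all four data modalities support
    parameter-recovery and null-calibration testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
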