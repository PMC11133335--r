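Package: eralfp
Title: Linear System Identification of Local Field Potentials via the
    Eigensystem Realization Algorithm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for quantifying the complexity of
    multi-channel local field potential (LFP) recordings with the
    Eigensystem Realization Algorithm (ERA). Long high-rate signals are
    denoised with a moving-average filter, downsampled through penalized
    piecewise-linear change-point detection, and re-interpolated to a
    coarse uniform grid; ERA then identifies a reduced discrete-time
    state-space model from block-Hankel matrices of the signal, and the
    Number of Stacks (the Hankel block-row count) is selected per
    recording phase by an AIC-driven grid search with nested fallback
    strategies. The selected Number of Stacks serves as a complexity
    measure that can be compared across experimental groups and phases
    with Mann-Whitney U and Welch t tests. A seeded synthetic LFP
    generator emulating phased, amplitude-decaying multi-channel
    recordings makes every stage testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
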