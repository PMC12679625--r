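Package: gaitlf
Title: Lyapunov-Floquet Dynamic Stability Analysis of Gait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the dynamic stability of human walking from
    motion-capture marker trajectories. Builds the medio-lateral
    centre-of-mass signal relative to a centre-of-pressure surrogate,
    reconstructs phase space with an optimized time-delay embedding,
    estimates the stride-to-stride monodromy matrix and its Floquet
    multipliers, derives long-term Lyapunov exponents from the Floquet
    exponents and short-term exponents with the Rosenstein divergence
    algorithm, and compares groups with an ANCOVA-based statistical
    battery with assumption checks, post-hoc per-group regressions and
    rank correlations against clinical severity scores. Ships synthetic
    gait, oscillator and chaotic-benchmark generators with closed-form
    ground truth so the whole pipeline is testable without laboratory
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    nortest,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
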