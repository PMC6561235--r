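Package: riskforage
Title: Simulation and Analysis of Risky Stay/Skip Foraging Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for simulating and analysing serial stay/skip foraging
    tasks with risky delay offers (the risk variant of the Web-Surf
    paradigm). Provides a deterministic session simulator with risky and
    non-risky offers, a generative model of synthetic subjects with known
    ground truth, leave-one-out Heaviside delay-threshold estimation,
    prospect-theoretic outcome framing, sequential mixed-effects choice,
    rating and reaction-time models with false-discovery-rate control,
    subject-level coefficient extraction with robust partial correlations
    against externalizing trait scores, and hyperbolic delay and
    probability discounting fits. All analyses are verifiable by parameter
    recovery on simulated populations.
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
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
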