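Package: calanmeals
Title: Feeding Behavior Monitoring at Gated Feed Bunks from Tilt-Logging Accelerometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to derive dairy-cow feeding behavior from 3-axis
    accelerometers mounted on electronically keyed feed-bunk doors (Calan
    gates). Converts logged per-axis acceleration to tilt angles, classifies
    open/closed door states against a tilt threshold, run-length encodes
    states into feeding bouts and between-feeding intervals, fits Gaussian
    mixture models to log-transformed intervals to derive a meal criterion
    (minimum intermeal interval) as the intersection of component densities,
    assembles and summarizes meals, validates sensor states against visual
    observation with Cohen's kappa and predictive values, and plans logger
    missions from memory capacity and sampling rate. Includes a seeded
    synthetic-data generator with ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tidyr
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
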