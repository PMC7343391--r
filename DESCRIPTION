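Package: flexcat
Title: Behavioral Modeling of Flexible Visual Categorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing choice behavior in block-structured visual
    categorization tasks in which the category boundary switches between
    blocks of trials. Implements a trial-by-trial dynamic decision-criterion
    choice model (with nested variants) and a stimulus-weighted
    reinforcement-learning alternative, a generative simulator of the
    boundary-switching task, constrained maximum-likelihood fitting with
    repeated balanced block-wise cross-validation and model comparison,
    parameter-recovery pipelines, psychometric and reversal-dynamics
    behavioral metrics, and ROC-based neural selectivity with
    pseudopopulation decoding of choice and sensory history. Everything is
    exercisable end-to-end on simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
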