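Package: sorsim
Title: Exact Stochastic Simulation of Self-Other Reorganization and Its
    Darwinian Extensions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An individual-based, exact (Gillespie) stochastic simulator of
    self-other reorganization (SOR): a fixed population of entities that
    acquire discrete products through external stimuli and spread them by
    pairwise horizontal transmission. The baseline corner of the model is
    equivalent to an SI epidemic (SIR without recovery); configurable
    extensions add recovery (SIR), product degradation, mixed beneficial /
    neutral / deleterious effect distributions, and Moran-type birth-death
    with fitness-proportional reproduction and imperfect inheritance.
    Closed-form oracles (SI fixation time, Moran fixation probability, SIR
    final size) validate the engine, and a regime classifier separates
    monomorphic ("community-based") from polymorphic ("individual-based")
    dynamics. Includes experiment presets, a replicate runner with CSV/JSON
    outputs, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
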