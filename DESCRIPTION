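Package: ethochain
Title: First-Order Markov Transition Analysis of Behavioral Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative ethology of mating behavior: builds
    first-order Markov transition matrices from per-trial behavioral event
    sequences (including BORIS-style event exports), applies an occurrence
    inclusion rule, computes expected transition frequencies, per-cell
    chi-square statistics, transition percentages and significance flags,
    segments sequences into premating/mating/postmating phases via marker
    transitions, compares groups with continuity-corrected two-proportion
    z-tests and summary-statistic t-tests, renders phase-colored ethogram
    (kinematic) diagrams in the DOT graph language, and simulates
    phase-structured semi-Markov behavioral sequences for end-to-end
    validation. Ships transcriptions of a published beetle mating-behavior
    ethogram study's repertoire and transition tables as reference fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
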