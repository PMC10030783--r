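Package: mycosim
Title: Excitation Dynamics and Spike Analysis for Fungal Insole Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates FitzHugh-Nagumo excitation dynamics on conductive
    templates derived from images of mycelium networks (or from a synthetic
    hyphal-growth model) shaped as insoles, with virtual-electrode read-outs,
    activity and coverage-frequency statistics, and extraction of Boolean
    logic gates from cross-scenario spike patterns. Also provides the
    matching analysis pipeline for logger-format electrophysiological
    recordings: prominence-based spike detection, windowed spike censuses,
    inter-spike-interval histograms and amplitude-by-load-condition
    summaries, together with a seeded synthetic recording generator with
    planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    withr,
    EBImage,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
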