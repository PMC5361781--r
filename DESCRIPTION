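Package: microstab
Title: Temporal Stability Analysis of Longitudinal Microbiome Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the temporal stability of microbial communities from
    longitudinal taxa abundance tables. Fits Taylor's power law (SD = V * mean^beta)
    to per-taxon temporal fluctuations with an errors-in-variables bootstrap,
    standardizes each subject's (V, beta) against the healthy reference group of
    its own study, models community dynamics with a Langevin equation whose
    stationary Fokker-Planck density classifies a microbiota as stable (ordered)
    or unstable (noise-induced disordered) phase, and computes rank-stability
    diagnostics (rank stability index, rank and difference variability) over
    time. Ships seeded synthetic-community generators (Poisson, exponential,
    exact Taylor, Langevin cohorts) so the full pipeline is testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    minpack.lm,
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
    yaml
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
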