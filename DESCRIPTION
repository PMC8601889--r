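Package: planktonEDM
Title: Predictability of Aggregated Plankton Time Series by Empirical
    Dynamic Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for asking whether summing noisy population time series
    into multi-species assemblages improves one-month-ahead forecast skill.
    Implements univariate simplex projection on delay embeddings with
    leave-one-out cross-validation and embedding-dimension selection,
    seasonal-climatology surrogate null models, Monte-Carlo assemblage
    resampling experiments (random, functional-group and cell-size
    strategies, exclusion filters, coefficient-of-variation diagnostics),
    two generative community models (a seasonal signal plus observational
    noise, and a stochastic Lotka-Volterra competition model with seasonal
    carrying capacity and monthly process noise), and a synthetic generator
    emulating the shape of a long-term coastal phytoplankton monitoring
    dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
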