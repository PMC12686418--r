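Package: ioertmc
Title: Monte Carlo Dosimetry for Intraoperative Electron Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale dosimetry toolkit for intraoperative electron
    radiotherapy (IOERT). Provides a simplified condensed-history Monte Carlo
    electron transport engine with a parametric accelerator-head model and
    phase-space recording/replay, percentage-depth-dose and profile extraction
    with detector-volume averaging, gamma-index (3%/3 mm) curve comparison,
    iterative source-parameter tuning against commissioning-style reference
    curves, output-factor and air-gap correction computation with
    uncertainty propagation, and out-of-field organ dosimetry on a MIRD-style
    anthropomorphic thorax phantom with shielding-disk misalignment analysis.
    A synthetic-reference generator produces commissioning-like curves and
    film-like images so the full pipeline is testable without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
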