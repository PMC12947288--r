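Package: hterank
Title: Z-Score Reagent Ranking for High-Throughput Experimentation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analyzing high-throughput experimentation (HTE) reaction
    screening data. Normalizes LC-MS peak areas to product area percent,
    collapses multi-sample time/temperature series, applies the plate-inclusion
    filter, computes per-transformation z-scores, and ranks reagents (ligands,
    catalysts, bases, solvents, and base-solvent combinations) by the median of
    their pooled top-n z-scores. Includes dataset diagnostics (skewness,
    Shapiro-Wilk normality, coverage matrices), a synthetic reaction-campaign
    generator with known ground truth for validation, and command-line entry
    points for ranking, diagnostics, simulation, and peak normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    purrr,
    rlang,
    stringi,
    stats,
    utils,
    e1071,
    ggplot2,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
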