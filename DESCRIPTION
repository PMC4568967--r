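Package: metacoex
Title: Differential Correlation Network Analysis of Diet and Age Effects on the Metabolome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing untargeted LC-MS metabolomic feature tables from
    dietary-restriction aging studies. Implements the full chain from quality
    control (log transformation, sample-network outlier removal, signal-to-noise
    and missingness filters, imputation, centering) through per-feature linear
    models of diet and age effects with false-discovery-rate control and the
    reversal-quadrant analysis, ANCOVA screening for metabolite pairs whose
    correlation (but not mean) responds to diet, differential (DiffCoEx-style)
    and preserved (SimCoEx-style) correlation-network module detection with
    permutation significance, and m/z-based metabolite-set enrichment. A seeded
    synthetic-data generator emulating a two-diet, multi-age, multi-tissue
    Drosophila design makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    sva,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    igraph,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
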