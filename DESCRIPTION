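Package: ratiometrics
Title: Ratiometric Gene Co-Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gene co-expression through the stability of pairwise
    expression ratios. For each gene pair the coefficient of variation of
    both expression ratios (A/B and B/A) is computed, a stringency gate on
    their discrepancy (delta-CV) selects ratiometric pairs, and the
    magnitude of the ratio CVs ranks them. Includes Pearson, Spearman and
    binned mutual-information baselines, all-pairs screening over filtered
    expression matrices, stringency-sweep co-expression graph construction,
    gene-set and ontology enrichment scoring with permutation nulls, and
    the validating simulations (range restriction, bivariate-normal sweeps,
    independent-pair false-positive nulls, planted-pair fixtures).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
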