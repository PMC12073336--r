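Package: bevscore
Title: Beverage Scoring Under the Original and Updated Nutri-Score Algorithms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes Nutri-Score Nutrient Profiling Model (NS-NPM) points,
    total scores and letter grades for non-alcoholic beverages under both the
    original (2015) and updated (2023) algorithms, including the 2015
    food-scale special case for milk, milkshakes and plant-based drinks and
    the 2023 non-nutritive-sweetener penalty. Provides validated CSV import
    of per-100 mL composition tables with the conservative zero-fiber
    imputation rule, a seeded synthetic beverage-market generator emulating
    published per-category nutrient distributions, and a paired comparison
    pipeline (relative score variation, Wilcoxon signed-rank, Spearman rank
    consistency, letter cross-tabulation, Cohen's kappa agreement, chi-square
    distribution tests and color-count discrimination) with tabular and
    long-format exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
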