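#' Relative variation between paired scores
#'
#' Per-product relative variation, `((score_2023 - score_2015) / score_2015)
#' x 100`. Undefined (returned as `NA`) when the 2015 score is 0; such
#' products are excluded from aggregation and counted.
#'
#' @param score_2015,score_2023 Integer vectors of paired totals.
#' @return Numeric vector of percentages, `NA` where the denominator is 0.
#' @export
#' @examples
#' relative_variation(c(1, 11, 0), c(4, 10, 5)) # 300, -9.09..., NA
relative_variation <- function(score_2015, score_2023) {
  stopifnot(length(score_2015) == length(score_2023))
  ifelse(score_2015 == 0, NA_real_,
         (score_2023 - score_2015) / score_2015 * 100)
}

#' Wilcoxon signed-rank test on paired scores
#'
#' Two-sided paired test of the within-product score difference between the
#' two algorithm versions. Zero differences are dropped and ties mid-ranked.
#' The exact distribution is used for 25 or fewer non-zero differences
#' without ties; otherwise the normal approximation with continuity and tie
#' correction. A sample whose differences are all zero is flagged degenerate
#' and reported as p = 1.
#'
#' @param score_2015,score_2023 Paired integer vectors (n >= 1).
#' @param exact_max Largest number of non-zero differences for which the
#'   exact distribution is attempted (default 25).
#' @return A list: `statistic` (V, sum of positive ranks of
#'   `score_2023 - score_2015`), `p_value`, `n_nonzero`, `method`,
#'   `degenerate`.
#' @export
#' @examples
#' wilcoxon_signed_rank(1:6, c(2, 4, 6, 8, 10, 12))$p_value # 0.03125
wilcoxon_signed_rank <- function(score_2015, score_2023, exact_max = 25) {
  stopifnot(length(score_2015) == length(score_2023),
            length(score_2015) >= 1)
  d <- score_2023 - score_2015
  nz <- d[d != 0]
  if (length(nz) == 0) {
    return(list(statistic = 0, p_value = 1, n_nonzero = 0L,
                method = "degenerate", degenerate = TRUE))
  }
  use_exact <- length(nz) <= exact_max && !any(duplicated(abs(nz)))
  # zeros are dropped here (Wilcoxon's convention) so the exact branch
  # remains available to the underlying test
  ht <- suppressWarnings(
    wilcox.test(nz, exact = use_exact, correct = TRUE)
  )
  list(statistic = unname(ht$statistic),
       p_value = min(1, unname(ht$p.value)),
       n_nonzero = length(nz),
       method = if (use_exact) "exact" else "normal approximation",
       degenerate = FALSE)
}

#' Spearman rank correlation of paired scores
#'
#' Tie-corrected Spearman coefficient: the product-moment correlation of
#' mid-ranks. Ties are the norm here since totals are small integers.
#'
#' @param score_2015,score_2023 Paired vectors (n >= 2).
#' @return Numeric rho in \[-1, 1\]; `NA` (with a warning) when either
#'   margin has zero variance.
#' @export
#' @examples
#' spearman_rho(c(1, 2, 3), c(2, 4, 6)) # 1
spearman_rho <- function(score_2015, score_2023) {
  stopifnot(length(score_2015) == length(score_2023),
            length(score_2015) >= 2)
  if (length(unique(score_2015)) < 2 || length(unique(score_2023)) < 2) {
    warning("zero variance in one margin; Spearman undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(score_2015, score_2023, method = "spearman")
}

#' Cross-tabulate letters across versions
#'
#' 5 x 5 contingency table of (2015 letter, 2023 letter), over all records or
#' one category.
#'
#' @param records Comparison tibble with `letter_2015`, `letter_2023` (and
#'   `category` when filtering).
#' @param category Optional category identifier to filter on.
#' @return A 5 x 5 `table` (rows: 2015 letters A–E; columns: 2023).
#' @export
letter_crosstab <- function(records, category = NULL) {
  if (!is.null(category)) {
    records <- records[records$category == category, , drop = FALSE]
  }
  if (nrow(records) == 0) stop("no records to tabulate", call. = FALSE)
  table(factor(records$letter_2015, levels = .LETTERS),
        factor(records$letter_2023, levels = .LETTERS),
        dnn = c("letter_2015", "letter_2023"))
}

#' Cohen's kappa for a letter cross-tabulation
#'
#' Chance-corrected agreement, `(p_obs - p_exp) / (1 - p_exp)`. Unweighted by
#' default; linear weights are available since letters are ordinal. When the
#' expected agreement is 1 (all mass in one row and column), kappa is defined
#' as 1 for a perfectly diagonal table and `NA` otherwise.
#'
#' @param crosstab Square contingency table/matrix (e.g. [letter_crosstab()]).
#' @param weights `"unweighted"` (default) or `"linear"`.
#' @return A list: `kappa` in \[-1, 1\], `percent` (`kappa` x 100, the style
#'   agreement is commonly reported in), `p_obs`, `p_exp`.
#' @export
#' @examples
#' cohen_kappa(matrix(c(20, 10, 5, 15), 2))$kappa # 0.40
cohen_kappa <- function(crosstab, weights = c("unweighted", "linear")) {
  weights <- match.arg(weights)
  m <- as.matrix(crosstab)
  if (nrow(m) != ncol(m)) stop("crosstab must be square", call. = FALSE)
  n <- sum(m)
  if (n < 1) stop("empty crosstab", call. = FALSE)
  k <- nrow(m)
  w <- if (weights == "unweighted") {
    diag(k)
  } else {
    1 - abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  }
  p <- m / n
  rs <- rowSums(p); cs <- colSums(p)
  p_obs <- sum(w * p)
  p_exp <- sum(w * outer(rs, cs))
  kappa <- if (p_exp >= 1 - 1e-12) {
    if (p_obs >= 1 - 1e-12) 1 else NA_real_
  } else {
    (p_obs - p_exp) / (1 - p_exp)
  }
  list(kappa = kappa, percent = kappa * 100, p_obs = p_obs, p_exp = p_exp)
}

#' Chi-square test on letter distributions
#'
#' Pearson chi-square test of homogeneity between the 2015 and 2023 letter
#' count vectors (expected counts from the pooled margins, no continuity
#' correction). Letters absent from both versions are dropped, so
#' df = (non-empty letters - 1). Warns when any expected count falls
#' below 5.
#'
#' @param counts_2015,counts_2023 Named or positional count vectors over the
#'   same letter support.
#' @return A list: `statistic`, `df`, `p_value`, `low_expected` (logical).
#' @export
#' @examples
#' chi_square_letters(c(10, 0), c(0, 10))$statistic # 20
chi_square_letters <- function(counts_2015, counts_2023) {
  stopifnot(length(counts_2015) == length(counts_2023))
  if (sum(counts_2015) + sum(counts_2023) == 0) {
    stop("zero total count", call. = FALSE)
  }
  keep <- (counts_2015 + counts_2023) > 0
  m <- rbind(v2015 = counts_2015[keep], v2023 = counts_2023[keep])
  if (sum(keep) < 2) {
    return(list(statistic = 0, df = 0L, p_value = 1, low_expected = FALSE))
  }
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), df = as.integer(ht$parameter),
       p_value = unname(ht$p.value), low_expected = any(ht$expected < 5))
}

#' Build paired comparison records
#'
#' One record per product: both totals and letters plus the per-product
#' relative variation.
#'
#' @param scores Tibble from [score_products()] with both versions.
#' @return A tibble of comparison records.
#' @export
compare_scores <- function(scores) {
  need <- c("product_id", "category", "score_2015", "letter_2015",
            "score_2023", "letter_2023")
  missing_cols <- setdiff(need, names(scores))
  if (length(missing_cols) > 0) {
    stop("scores table lacks: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    product_id = scores$product_id,
    category = scores$category,
    score_2015 = scores$score_2015,
    letter_2015 = scores$letter_2015,
    score_2023 = scores$score_2023,
    letter_2023 = scores$letter_2023,
    relative_variation_pct = relative_variation(scores$score_2015,
                                                scores$score_2023)
  )
}

# aggregate per-product relative variations for one category
aggregate_relvar <- function(s15, s23, method) {
  rv <- relative_variation(s15, s23)
  switch(method,
    "mean-excluding-zeros" = mean(rv, na.rm = TRUE),
    "median-excluding-zeros" = median(rv, na.rm = TRUE),
    "of-medians" = {
      m15 <- median(s15)
      if (m15 == 0) NA_real_ else (median(s23) - m15) / m15 * 100
    },
    stop("unknown relvar method '", method, "'", call. = FALSE)
  )
}

#' Per-category comparison summary
#'
#' One summary row per beverage category: medians and ranges of both scores,
#' aggregated relative variation, Wilcoxon signed-rank p-value, Spearman
#' rank-consistency coefficient, modal letters, kappa agreement between the
#' two letter assignments, and the number of distinct letters (colors) each
#' version uses within the category — the discrimination measure. Also
#' returns the overall percentage-point shift per letter between versions
#' and a long-format score export for box-plot rendering.
#'
#' @param records Tibble from [compare_scores()].
#' @param relvar Aggregation for the per-product relative variation:
#'   `"mean-excluding-zeros"` (default), `"median-excluding-zeros"` or
#'   `"of-medians"` (variation of the category medians). Products with a 2015
#'   score of 0 are excluded from the first two and counted in
#'   `n_relvar_excluded`.
#' @param kappa_weights Passed to [cohen_kappa()].
#' @return A list of class `ns_summary`: `by_category` (tibble, one row per
#'   category), `letter_shift` (per-letter percentage points 2015 vs 2023 and
#'   their difference), `long_scores` (long-format tibble for plotting) and
#'   `letter_cutoffs` (both versions' score cut-offs, for plot annotation).
#' @export
#' @examples
#' mkt <- simulate_market(seed = 1, scale = 0.05)
#' summ <- build_summary(compare_scores(score_products(mkt)))
#' summ$by_category[, c("category", "median_2015", "median_2023")]
build_summary <- function(records,
                          relvar = c("mean-excluding-zeros",
                                     "median-excluding-zeros", "of-medians"),
                          kappa_weights = "unweighted") {
  relvar <- match.arg(relvar)
  if (nrow(records) == 0) stop("no records to summarise", call. = FALSE)

  summarise_one <- function(g) {
    wt <- wilcoxon_signed_rank(g$score_2015, g$score_2023)
    rho <- if (nrow(g) >= 2) suppressWarnings(
      spearman_rho(g$score_2015, g$score_2023)) else NA_real_
    kap <- cohen_kappa(letter_crosstab(g), weights = kappa_weights)
    modal <- function(x) names(sort(table(x), decreasing = TRUE))[1]
    tibble::tibble(
      n = nrow(g),
      median_2015 = median(g$score_2015),
      min_2015 = min(g$score_2015), max_2015 = max(g$score_2015),
      median_2023 = median(g$score_2023),
      min_2023 = min(g$score_2023), max_2023 = max(g$score_2023),
      relative_variation_pct = aggregate_relvar(g$score_2015, g$score_2023,
                                                relvar),
      n_relvar_excluded = sum(g$score_2015 == 0),
      wilcoxon_p = wt$p_value,
      wilcoxon_degenerate = wt$degenerate,
      spearman_rho = rho,
      modal_letter_2015 = modal(g$letter_2015),
      modal_letter_2023 = modal(g$letter_2023),
      kappa = kap$kappa,
      kappa_pct = kap$percent,
      colors_2015 = length(unique(g$letter_2015)),
      colors_2023 = length(unique(g$letter_2023))
    )
  }
  by_category <- records |>
    dplyr::group_by(.data$category) |>
    dplyr::group_modify(~ summarise_one(.x)) |>
    dplyr::ungroup()

  pct <- function(letters) {
    100 * as.vector(table(factor(letters, levels = .LETTERS))) /
      length(letters)
  }
  letter_shift <- tibble::tibble(
    letter = .LETTERS,
    pct_2015 = pct(records$letter_2015),
    pct_2023 = pct(records$letter_2023)
  )
  letter_shift$shift_pp <- letter_shift$pct_2023 - letter_shift$pct_2015

  long_scores <- tidyr::pivot_longer(
    records[, c("product_id", "category", "score_2015", "score_2023")],
    cols = c("score_2015", "score_2023"),
    names_to = "version", names_prefix = "score_", values_to = "score")

  cutoffs <- function(name) {
    sc <- load_scale(name)
    tibble::tibble(scale = name,
                   letter = sc$letters$letter,
                   upper = sc$letters$upper)
  }
  out <- list(by_category = by_category, letter_shift = letter_shift,
              long_scores = long_scores,
              letter_cutoffs = dplyr::bind_rows(cutoffs("beverage_2015"),
                                                cutoffs("beverage_2023")))
  class(out) <- "ns_summary"
  out
}

#' @export
print.ns_summary <- function(x, ...) {
  cat("<ns_summary> ", nrow(x$by_category), " categories, ",
      sum(x$by_category$n), " products\n", sep = "")
  print(x$by_category[, c("category", "n", "median_2015", "median_2023",
                          "relative_variation_pct", "wilcoxon_p",
                          "spearman_rho", "kappa_pct")])
  invisible(x)
}

#' Write all comparison outputs to a directory
#'
#' Emits the per-category summary, the per-letter shift table, the
#' long-format score export and one letter crosstab CSV per category.
#'
#' @param summary An `ns_summary` from [build_summary()].
#' @param records The records the summary was built from.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_summary <- function(summary, records, out_dir) {
  stopifnot(inherits(summary, "ns_summary"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(summary$by_category,
                   file.path(out_dir, "category_summary.csv"), progress = FALSE)
  readr::write_csv(summary$letter_shift,
                   file.path(out_dir, "letter_shift.csv"), progress = FALSE)
  readr::write_csv(summary$long_scores,
                   file.path(out_dir, "scores_long.csv"), progress = FALSE)
  for (cat in sort(unique(records$category))) {
    tab <- as.data.frame.matrix(letter_crosstab(records, cat))
    tab <- cbind(letter_2015 = rownames(tab), tibble::as_tibble(tab))
    readr::write_csv(tab, file.path(out_dir,
                                    paste0("crosstab_", cat, ".csv")),
                     progress = FALSE)
  }
  invisible(out_dir)
}
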