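test_that("relative variation follows the paired formula with zero-denominator exclusion", {
  expect_equal(relative_variation(1, 4), 300)
  expect_equal(relative_variation(11, 10), -100 / 11)
  expect_true(is.na(relative_variation(0, 5)))
  expect_equal(relative_variation(c(2, -2), c(3, -3)), c(50, 50))
})

test_that("Wilcoxon signed-rank matches brute-force enumeration and handles edge cases", {
  # 6 pairs with doubled scores: exact two-sided p = 0.03125
  res <- wilcoxon_signed_rank(1:6, c(2, 4, 6, 8, 10, 12))
  expect_equal(res$p_value, 0.03125)
  expect_identical(res$method, "exact")
  expect_equal(res$p_value, enumerate_wilcoxon_p(c(2, 4, 6, 8, 10, 12) - 1:6))

  # random small fixtures with distinct |d| agree with the enumeration oracle
  set.seed(101)
  for (i in 1:5) {
    d <- sample(1:30, 8) * sample(c(-1, 1), 8, replace = TRUE)
    res <- wilcoxon_signed_rank(rep(0, 8), d)
    expect_equal(res$p_value, enumerate_wilcoxon_p(d))
  }

  # a single non-zero pair: exact two-sided p = 1
  expect_equal(wilcoxon_signed_rank(0, 3)$p_value, 1)

  # all differences zero: degenerate, p = 1
  deg <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)

  # zero differences are dropped before ranking
  expect_equal(wilcoxon_signed_rank(c(0, 1:6), c(0, c(2, 4, 6, 8, 10, 12)))$p_value,
               0.03125)
})

test_that("exact and normal-approximation branches agree closely at n = 25", {
  set.seed(123)
  for (i in 1:20) {
    d <- sample(1:60, 25) * sample(c(-1, 1), 25, replace = TRUE)
    pe <- wilcoxon_signed_rank(rep(0, 25), d, exact_max = 25)$p_value
    pa <- wilcoxon_signed_rank(rep(0, 25), d, exact_max = 0)$p_value
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("Spearman rank consistency handles monotone, reversed and tied fixtures", {
  expect_equal(spearman_rho(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(spearman_rho(c(1, 1, 2), c(1, 1, 2)), 1)
  expect_warning(r <- spearman_rho(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_true(is.na(r))
  # invariant under strictly monotone transforms
  set.seed(5)
  x <- sample(-5:20, 30, replace = TRUE)
  expect_equal(spearman_rho(x, as.numeric(x)^3 + 7), 1)
  expect_equal(spearman_rho(x, exp(x / 10)), 1)
})

test_that("letter crosstabs count pairs and normalize", {
  rec <- tibble::tibble(
    category = "milk",
    letter_2015 = c("A", "B"), letter_2023 = c("B", "B"))
  tab <- letter_crosstab(rec)
  expect_identical(sum(tab), 2L)
  expect_identical(unname(tab["A", "B"]), 1L)
  expect_identical(unname(tab["B", "B"]), 1L)
  expect_identical(dim(tab), c(5L, 5L))
  expect_error(letter_crosstab(rec, category = "milkshakes"), "no records")
})

test_that("Cohen's kappa matches hand-computed and degenerate fixtures", {
  # printed 2x2 fixture: p_obs = 0.7, p_exp = 0.5 -> kappa 0.40
  tab <- matrix(c(20, 10, 5, 15), 2)
  expect_equal(cohen_kappa(tab)$kappa, 0.4)
  expect_equal(cohen_kappa(tab)$percent, 40)

  # perfect diagonal -> 1; exact marginal independence -> 0
  expect_equal(cohen_kappa(diag(c(3, 5, 9)))$kappa, 1)
  indep <- outer(c(10, 30), c(5, 15)) / 50
  expect_equal(cohen_kappa(indep)$kappa, 0)

  # single-cell table: defined as 1 when perfectly observed
  one <- matrix(c(7, 0, 0, 0), 2)
  expect_equal(cohen_kappa(one)$kappa, 1)

  # linear weights reward near-diagonal mass
  off <- matrix(c(0, 5, 5, 0), 2)
  expect_lte(cohen_kappa(off, weights = "linear")$kappa,
             cohen_kappa(off)$kappa + 1e-12)

  # independent cross-check against e1071's agreement coefficient
  skip_if_not_installed("e1071")
  mkt <- simulate_market(seed = 4, scale = 0.05)
  rec <- compare_scores(score_products(mkt))
  tab5 <- letter_crosstab(rec)
  expect_equal(cohen_kappa(tab5)$kappa,
               e1071::classAgreement(tab5)$kappa, tolerance = 1e-12)
})

test_that("chi-square on letter distributions matches hand computation", {
  same <- chi_square_letters(c(10, 20, 5), c(10, 20, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # [10,0] vs [0,10]: pooled expecteds all 5 -> statistic 20, df 1
  res <- chi_square_letters(c(10, 0), c(0, 10))
  expect_equal(res$statistic, 20)
  expect_identical(res$df, 1L)

  # permutation symmetry over letter order
  a <- c(12, 3, 9, 0, 1); b <- c(4, 8, 6, 2, 0)
  perm <- c(3, 1, 5, 2, 4)
  r1 <- chi_square_letters(a, b)
  r2 <- chi_square_letters(a[perm], b[perm])
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
  expect_true(r1$low_expected)

  expect_error(chi_square_letters(c(0, 0), c(0, 0)), "zero total")
})

test_that("category summaries aggregate paired records coherently", {
  # single category, single product
  one <- tibble::tibble(product_id = "m1", category = "milk",
                        score_2015 = 1L, letter_2015 = "B",
                        score_2023 = 3L, letter_2023 = "C")
  s <- build_summary(one)
  row <- s$by_category
  expect_identical(row$n, 1L)
  expect_equal(row$median_2015, 1)
  expect_equal(row$median_2023, 3)
  expect_equal(row$relative_variation_pct, 200)
  expect_true(row$wilcoxon_p <= 1)

  # synthetic batch: shift percentages sum to zero, kappa/rho in range
  mkt <- simulate_market(seed = 6, scale = 0.1)
  rec <- compare_scores(score_products(mkt))
  summ <- build_summary(rec)
  expect_equal(sum(summ$letter_shift$shift_pp), 0, tolerance = 1e-9)
  expect_equal(sum(summ$letter_shift$pct_2015), 100, tolerance = 1e-9)
  expect_equal(sum(summ$letter_shift$pct_2023), 100, tolerance = 1e-9)
  expect_true(all(summ$by_category$spearman_rho >= -1 &
                    summ$by_category$spearman_rho <= 1, na.rm = TRUE))
  expect_true(all(summ$by_category$kappa >= -1 & summ$by_category$kappa <= 1,
                  na.rm = TRUE))
  expect_identical(sum(summ$by_category$n), nrow(mkt))
  expect_true(all(summ$by_category$colors_2015 %in% 1:5))
  expect_true(all(summ$by_category$colors_2023 %in% 1:5))
  expect_identical(nrow(summ$long_scores), 2L * nrow(mkt))

  # relative-variation aggregation variants
  s_med <- build_summary(rec, relvar = "median-excluding-zeros")
  s_ofm <- build_summary(rec, relvar = "of-medians")
  expect_identical(nrow(s_med$by_category), nrow(s_ofm$by_category))
  # records with score_2015 == 0 are excluded and counted
  expect_identical(summ$by_category$n_relvar_excluded,
                   as.integer(tapply(rec$score_2015 == 0, rec$category, sum)[
                     summ$by_category$category]))
})

test_that("letters in comparison records are consistent with classify_score", {
  mkt <- simulate_market(seed = 8, scale = 0.05)
  sp <- score_products(mkt)
  rec <- compare_scores(sp)
  sc23 <- load_scale("beverage_2023")
  expect_identical(rec$letter_2023,
                   classify_score(rec$score_2023, sc23, mkt$is_water))
  for (sn in unique(sp$scale_used_2015)) {
    idx <- sp$scale_used_2015 == sn
    expect_identical(rec$letter_2015[idx],
                     classify_score(rec$score_2015[idx], load_scale(sn),
                                    mkt$is_water[idx]))
  }
})
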