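# shared fixtures and independent oracles

make_product <- function(...) {
  defaults <- list(product_id = "p1", category = "sugar_sweetened",
                   energy_kj = 0, sugars_g = 0, total_fat_g = 0, satfat_g = 0,
                   salt_g = 0, protein_g = 0, fiber_g = 0, fvl_percent = 0,
                   has_nns = FALSE, is_water = FALSE)
  utils::modifyList(defaults, list(...))
}

# independent band-lookup oracle: exhaustive linear scan over the band list
scan_points <- function(value, table) {
  vapply(value, function(v) {
    for (i in seq_along(table$thresholds)) {
      if (v <= table$thresholds[i]) return(table$points[i])
    }
    table$top_points
  }, integer(1))
}

# independent exact Wilcoxon oracle: enumerate all 2^n sign assignments of
# the absolute differences and compute the two-sided tail of W+ (valid for
# distinct non-zero |d|)
enumerate_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  min(1, 2 * min(p_ge, p_le))
}
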