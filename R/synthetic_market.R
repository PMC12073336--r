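# Two-piece triangular sampler honoring (min, median, max): a 50/50 mixture
# of a rising triangle on [min, med] and a falling triangle on [med, max],
# so the population median equals `med` exactly and the support is
# [min, max]. Degenerate pieces (min == med or med == max) collapse to the
# point mass / single triangle.
rtri2 <- function(n, min, med, max) {
  stopifnot(min <= med, med <= max)
  if (n == 0) return(numeric(0))
  if (min == max) return(rep(min, n))
  side_right <- runif(n) < 0.5
  u <- runif(n)
  x <- numeric(n)
  # rising density on [min, med], peak at med
  x[!side_right] <- min + (med - min) * sqrt(u[!side_right])
  # falling density on [med, max], peak at med
  x[side_right] <- med + (max - med) * (1 - sqrt(1 - u[side_right]))
  x
}

#' Default synthetic market specification
#'
#' One specification row per beverage category, transcribed from published
#' per-category nutrient marginals for the Spanish non-alcoholic beverage
#' market (median and min–max per 100 mL; energy in kcal), with category
#' sample sizes totalling 3432 products. The artificially sweetened category
#' has non-nutritive-sweetener prevalence 1; all other categories 0 (products
#' containing such sweeteners are by construction categorized as artificially
#' sweetened). These are synthetic emulation parameters, not a reproduction
#' of any real database's joint distribution.
#'
#' @param path Optional path to a JSON specification overriding the shipped
#'   defaults (same schema).
#' @return A tibble with one row per category: `category`, `label`, `n`,
#'   `nns_prevalence`, `water_flag_prevalence`, `fvl_mix_weight`, and
#'   `<nutrient>_med` / `_min` / `_max` columns for energy (kcal), sugars,
#'   total fat, saturated fat, salt, protein, fiber and the FVL percentage.
#' @export
#' @examples
#' default_category_specs()[, c("category", "n", "protein_g_med")]
default_category_specs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "market", "drink_base_synthetic.json",
                        package = "bevscore", mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  nutrients <- c("energy_kcal", "sugars_g", "total_fat_g", "satfat_g",
                 "salt_g", "protein_g", "fiber_g", "fvl_percent")
  rows <- lapply(raw$categories, function(cat) {
    row <- tibble::tibble(
      category = cat$category, label = cat$label, n = as.integer(cat$n),
      nns_prevalence = as.numeric(cat$nns_prevalence),
      water_flag_prevalence = as.numeric(cat$water_flag_prevalence),
      fvl_mix_weight = as.numeric(cat$fvl_mix_weight)
    )
    for (nu in nutrients) {
      tri <- as.numeric(unlist(cat[[nu]]))
      if (length(tri) != 3 || tri[2] > tri[1] || tri[1] > tri[3]) {
        stop("spec for '", cat$category, "', nutrient '", nu,
             "': need (median, min, max) with min <= median <= max",
             call. = FALSE)
      }
      row[[paste0(nu, "_med")]] <- tri[1]
      row[[paste0(nu, "_min")]] <- tri[2]
      row[[paste0(nu, "_max")]] <- tri[3]
    }
    row
  })
  spec <- dplyr::bind_rows(rows)
  if (any(spec$nns_prevalence < 0 | spec$nns_prevalence > 1) ||
      any(spec$water_flag_prevalence < 0 | spec$water_flag_prevalence > 1)) {
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  }
  spec
}

#' Sample synthetic products for one category
#'
#' Each nutrient is drawn from a two-piece triangular distribution with its
#' mode and median at the specification median, truncated to the
#' specification min–max. Saturated fat is clamped to total fat. Energy is
#' reconciled with the sampled macronutrients: the triangular draw is blended
#' 50/50 with the Atwater estimate (4 kcal/g sugars and protein, 9 kcal/g
#' fat, 2 kcal/g fiber), kept within 15% of the original draw, and
#' re-truncated to the specification range, preventing physically implausible
#' rows. For strongly bimodal FVL categories (juices), a share
#' `1 - fvl_mix_weight` of products is given 0% FVL.
#'
#' @param spec One row of [default_category_specs()].
#' @param n Number of products (default `spec$n`).
#' @param seed Optional integer seed (set it here only when sampling a single
#'   category; [simulate_market()] manages the stream across categories).
#' @return A tibble of `n` valid products with the standard column schema.
#' @export
#' @examples
#' spec <- default_category_specs()
#' sample_category(spec[spec$category == "legume_based", ], n = 5, seed = 42)
sample_category <- function(spec, n = spec$n, seed = NULL) {
  stopifnot(nrow(spec) == 1)
  if (length(n) != 1 || is.na(n) || n < 0) {
    stop("n must be a single non-negative integer", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)

  draw <- function(nu) {
    rtri2(n, spec[[paste0(nu, "_min")]], spec[[paste0(nu, "_med")]],
          spec[[paste0(nu, "_max")]])
  }
  # nutrients are reported at label precision (2 decimals; FVL 1), then
  # clamped back into the spec range so rounding never escapes the bounds
  label2 <- function(x, nu) {
    pmin(pmax(round(x, 2), spec[[paste0(nu, "_min")]]),
         spec[[paste0(nu, "_max")]])
  }
  sugars <- label2(draw("sugars_g"), "sugars_g")
  fat <- label2(draw("total_fat_g"), "total_fat_g")
  satfat <- pmin(label2(draw("satfat_g"), "satfat_g"), fat)
  salt <- label2(draw("salt_g"), "salt_g")
  protein <- label2(draw("protein_g"), "protein_g")
  fiber <- label2(draw("fiber_g"), "fiber_g")

  fvl <- draw("fvl_percent")
  if (spec$fvl_mix_weight < 1 && n > 0) {
    fvl[runif(n) >= spec$fvl_mix_weight] <- 0
  }
  fvl <- pmin(pmax(round(fvl, 1), 0), spec$fvl_percent_max)

  kcal <- draw("energy_kcal")
  atwater <- 4 * sugars + 9 * fat + 4 * protein + 2 * fiber
  blended <- 0.5 * kcal + 0.5 * atwater
  blended <- pmin(pmax(blended, 0.85 * kcal), 1.15 * kcal)
  kcal <- pmin(pmax(round(blended, 2), spec$energy_kcal_min),
               spec$energy_kcal_max)

  tibble::tibble(
    product_id = sprintf("%s_%04d", spec$category, seq_len(n)),
    category = spec$category,
    energy_kj = round(kcal * 4.184, 2),
    sugars_g = sugars,
    total_fat_g = fat,
    satfat_g = satfat,
    salt_g = salt,
    protein_g = protein,
    fiber_g = fiber,
    fvl_percent = fvl,
    has_nns = runif(n) < spec$nns_prevalence,
    is_water = runif(n) < spec$water_flag_prevalence
  )
}

#' Simulate a synthetic beverage market
#'
#' Generates a full 12-category product table whose per-category marginals
#' emulate the published Spanish beverage-market summaries. The default scale
#' reproduces the published category counts (3432 products in total); smaller
#' `scale` values shrink every category proportionally (minimum one product
#' per category) for fast tests. Fully reproducible under a fixed seed.
#'
#' @param seed Integer seed for the generator.
#' @param scale Positive scaling factor on category sizes (default 1).
#' @param specs Specification tibble (default [default_category_specs()]).
#' @return A tibble of products ready for [score_products()].
#' @export
#' @examples
#' mkt <- simulate_market(seed = 1, scale = 0.05)
#' table(mkt$category)
simulate_market <- function(seed, scale = 1, specs = default_category_specs()) {
  if (missing(seed) || length(seed) != 1 || is.na(seed)) {
    stop("an integer seed is required for reproducibility", call. = FALSE)
  }
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  set.seed(as.integer(seed))
  parts <- lapply(seq_len(nrow(specs)), function(i) {
    spec <- specs[i, , drop = FALSE]
    sample_category(spec, n = max(1L, as.integer(round(spec$n * scale))))
  })
  dplyr::bind_rows(parts)
}
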