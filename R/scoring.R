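# map a product table's columns onto a scale's component inputs
component_values <- function(df, comp_name) {
  switch(comp_name,
    energy = df$energy_kj,
    sugars = df$sugars_g,
    satfat = df$satfat_g,
    sodium = df$salt_g * .SALT_TO_SODIUM_MG,
    salt   = df$salt_g,
    nns    = as.numeric(df$has_nns),
    protein = df$protein_g,
    fiber  = df$fiber_g,
    fvl    = df$fvl_percent,
    stop("no column mapping for component '", comp_name, "'", call. = FALSE)
  )
}

# vectorised scoring of a product tibble under one ns_scale
score_with_scale <- function(df, scale, official_protein_rule = FALSE) {
  comp_names <- names(scale$components)
  pts <- vapply(comp_names, function(nm) {
    if (nm == "fvl") {
      fvl_points(component_values(df, nm), scale)
    } else {
      component_points(component_values(df, nm), scale$components[[nm]])
    }
  }, integer(nrow(df)))
  pts <- matrix(pts, nrow = nrow(df),
                dimnames = list(NULL, comp_names))

  fav <- vapply(scale$components, function(c) c$polarity == "favorable",
                logical(1))
  unfavorable_total <- as.integer(rowSums(pts[, !fav, drop = FALSE]))
  fav_pts <- pts[, fav, drop = FALSE]
  if (official_protein_rule && "protein" %in% colnames(fav_pts)) {
    # official exception: protein is withheld when the unfavorable total is
    # high (>= 11) unless the fruit/veg/legume component is at its maximum
    withhold <- unfavorable_total >= 11L &
      pts[, "fvl"] < scale$components$fvl$top_points
    fav_pts[withhold, "protein"] <- 0L
  }
  favorable_total <- as.integer(rowSums(fav_pts))
  total <- unfavorable_total - favorable_total

  out <- tibble::tibble(
    product_id = df$product_id,
    scale_used = scale$name,
    unfavorable_total = unfavorable_total,
    favorable_total = favorable_total,
    total_score = total,
    letter = classify_score(total, scale, df$is_water)
  )
  pts_tbl <- tibble::as_tibble(as.data.frame(pts))
  names(pts_tbl) <- paste0("pts_", names(pts_tbl))
  dplyr::bind_cols(out, pts_tbl)
}

as_product_row <- function(product) {
  defaults <- list(product_id = "p1", category = "sugar_sweetened",
                   energy_kj = 0, sugars_g = 0, total_fat_g = 0, satfat_g = 0,
                   salt_g = 0, protein_g = 0, fiber_g = 0, fvl_percent = 0,
                   has_nns = FALSE, is_water = FALSE)
  product <- utils::modifyList(defaults, as.list(product))
  tibble::as_tibble(product[names(defaults)])
}

breakdown_from_row <- function(row, version) {
  pts_cols <- grep("^pts_", names(row), value = TRUE)
  pts <- as.integer(row[1, pts_cols])
  names(pts) <- sub("^pts_", "", pts_cols)
  structure(list(
    product_id = row$product_id,
    version = version,
    scale_used = row$scale_used,
    component_points = pts,
    unfavorable_total = row$unfavorable_total,
    favorable_total = row$favorable_total,
    total_score = row$total_score,
    letter = row$letter
  ), class = "ns_breakdown")
}

#' @export
print.ns_breakdown <- function(x, ...) {
  cat("<ns_breakdown> ", x$product_id, " [", x$version, ", ", x$scale_used,
      "]\n", sep = "")
  cat("  points: ",
      paste(names(x$component_points), x$component_points, sep = "=",
            collapse = " "), "\n", sep = "")
  cat("  total ", x$total_score, " (unfavorable ", x$unfavorable_total,
      " - favorable ", x$favorable_total, ") -> ", x$letter, "\n", sep = "")
  invisible(x)
}

#' Score a single beverage under the original (2015) algorithm
#'
#' Computes per-component points, the total score (unfavorable minus
#' favorable) and the letter grade. Plant-based beverages, milk and
#' milkshakes are scored on the general-food bands; all other categories on
#' the beverage bands. Sodium is derived internally from declared salt
#' (sodium mg = salt g x 400). Non-nutritive sweeteners play no role in this
#' version.
#'
#' @param product A named list or one-row data frame with fields
#'   `product_id`, `category`, `energy_kj`, `sugars_g`, `total_fat_g`,
#'   `satfat_g`, `salt_g`, `protein_g`, `fiber_g`, `fvl_percent`, `has_nns`,
#'   `is_water`. Missing fields default to zero/`FALSE`.
#' @param official_protein_rule If `TRUE`, apply the official
#'   protein-counting exception (protein points withheld when the unfavorable
#'   total is >= 11 and the fruit/vegetable/legume component is below its
#'   maximum). Default `FALSE`: plain subtraction.
#' @return An `ns_breakdown` object.
#' @export
#' @examples
#' score_2015(list(product_id = "cola", category = "sugar_sweetened",
#'                 energy_kj = 180, sugars_g = 10.6))
score_2015 <- function(product, official_protein_rule = FALSE) {
  row <- as_product_row(product)
  scale <- load_scale(select_scale_2015(row$category))
  breakdown_from_row(score_with_scale(row, scale, official_protein_rule),
                     "v2015")
}

#' Score a single beverage under the updated (2023) algorithm
#'
#' All twelve categories — including plant-based drinks, milk and milkshakes
#' — are scored on the updated beverage bands. Salt is scored directly
#' (0–20 points), and products containing non-nutritive sweeteners incur a
#' flat 4-point penalty.
#'
#' @inheritParams score_2015
#' @return An `ns_breakdown` object.
#' @export
#' @examples
#' score_2023(list(product_id = "zero-cola", category = "artificially_sweetened",
#'                 energy_kj = 2, has_nns = TRUE))
score_2023 <- function(product, official_protein_rule = FALSE) {
  row <- as_product_row(product)
  select_scale_2015(row$category)  # validates the category label
  scale <- load_scale("beverage_2023")
  breakdown_from_row(score_with_scale(row, scale, official_protein_rule),
                     "v2023")
}

#' Score a product table under one or both algorithm versions
#'
#' Vectorised scoring of a composition table. With `version = "both"` the
#' result carries paired columns (`score_2015`, `letter_2015`, `score_2023`,
#' `letter_2023`) plus per-component point columns prefixed `p2015_` /
#' `p2023_`, ready for [compare_scores()].
#'
#' @param products A data frame of products (see [read_products()] for the
#'   column schema). `fiber_g` must already be imputed (no `NA`).
#' @param version `"both"` (default), `"2015"` or `"2023"`.
#' @param official_protein_rule Passed to the per-version scorers.
#' @return A tibble, one row per product.
#' @export
#' @examples
#' mkt <- simulate_market(seed = 1, scale = 0.02)
#' head(score_products(mkt))
score_products <- function(products, version = c("both", "2015", "2023"),
                           official_protein_rule = FALSE) {
  version <- match.arg(version)
  df <- tibble::as_tibble(products)
  check_products(df)

  one_version <- function(v) {
    if (v == "2015") {
      scale_names <- select_scale_2015(df$category)
      parts <- lapply(unique(scale_names), function(sn) {
        sub <- df[scale_names == sn, , drop = FALSE]
        score_with_scale(sub, load_scale(sn), official_protein_rule)
      })
      res <- dplyr::bind_rows(parts)
    } else {
      res <- score_with_scale(df, load_scale("beverage_2023"),
                              official_protein_rule)
    }
    res <- res[match(df$product_id, res$product_id), , drop = FALSE]
    tag <- paste0("p", if (v == "2015") "2015" else "2023", "_")
    names(res) <- sub("^pts_", tag, names(res))
    suffix <- if (v == "2015") "_2015" else "_2023"
    dplyr::rename_with(res,
      ~ paste0(sub("total_score", "score", sub("letter", "letter", .x)),
               suffix),
      dplyr::all_of(c("scale_used", "unfavorable_total", "favorable_total",
                      "total_score", "letter")))
  }

  base <- df[, intersect(c("product_id", "category", "energy_kj", "sugars_g",
                           "total_fat_g", "satfat_g", "salt_g", "protein_g",
                           "fiber_g", "fvl_percent", "has_nns", "is_water"),
                         names(df)), drop = FALSE]
  out <- base
  if (version %in% c("both", "2015")) {
    out <- dplyr::left_join(out, one_version("2015"), by = "product_id")
  }
  if (version %in% c("both", "2023")) {
    out <- dplyr::left_join(out, one_version("2023"), by = "product_id")
  }
  tibble::as_tibble(out)
}

# structural validation shared by the scorer and reader; stops on violation
check_products <- function(df) {
  required <- c("product_id", "category", "energy_kj", "sugars_g",
                "total_fat_g", "satfat_g", "salt_g", "protein_g", "fiber_g",
                "fvl_percent", "has_nns", "is_water")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$product_id)) {
    stop("product_id values must be unique", call. = FALSE)
  }
  select_scale_2015(df$category)  # validates labels
  num <- c("energy_kj", "sugars_g", "total_fat_g", "satfat_g", "salt_g",
           "protein_g", "fiber_g", "fvl_percent")
  for (col in num) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0)) {
      stop("column '", col, "' must be numeric, complete and non-negative",
           call. = FALSE)
    }
  }
  if (any(df$satfat_g > df$total_fat_g)) {
    stop("saturated fat exceeds total fat for some products", call. = FALSE)
  }
  if (any(df$fvl_percent > 100)) {
    stop("fvl_percent above 100 for some products", call. = FALSE)
  }
  invisible(df)
}
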