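#' Read and validate a product composition table
#'
#' Reads a per-100 mL beverage composition CSV, converts energy units,
#' applies the conservative fiber imputation rule (missing fiber is taken as
#' zero, since fiber declaration is not mandatory on EU labels) and validates
#' every row. Rows violating the composition invariants (negative nutrients,
#' saturated fat above total fat, unknown category, out-of-range FVL
#' percentage, duplicate ids) are rejected with row-level diagnostics rather
#' than aborting the read.
#'
#' Expected columns: `product_id`, `category`, `energy_kj` and/or
#' `energy_kcal`, `sugars_g`, `total_fat_g`, `satfat_g`, `salt_g`,
#' `protein_g`; optional: `fiber_g`, `fvl_percent` (default 0, logged),
#' `has_nns`, `is_water`, `ingredients_text`. When only kcal is declared, kJ
#' is derived as kcal x 4.184; when both are declared and disagree by more
#' than 2%, the regulated unit (kJ) is preferred with a warning. When
#' `has_nns` is absent but `ingredients_text` is present, the flag is derived
#' with [derive_flags()].
#'
#' @param path Path to a CSV file (UTF-8, `.` decimal by default).
#' @param decimal_mark Decimal mark, `"."` (default) or `","` for
#'   Spanish-locale exports.
#' @param delim Field delimiter (default `","`; `";"` pairs naturally with
#'   `decimal_mark = ","`).
#' @return A list of class `product_table`: `products` (validated tibble),
#'   `rejected` (tibble with a `reason` column), `fiber_imputed_count`,
#'   `fvl_defaulted_count` and `provenance`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(product_id = "j1", category = "fruit_juices",
#'                      energy_kcal = 45, sugars_g = 9.9, total_fat_g = 0.1,
#'                      satfat_g = 0, salt_g = 0.01, protein_g = 0.3,
#'                      fvl_percent = 100), f, row.names = FALSE)
#' read_products(f)$products
read_products <- function(path, decimal_mark = ".", delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    locale = readr::locale(decimal_mark = decimal_mark,
                           grouping_mark = if (decimal_mark == ",") "." else ","))
  raw <- tibble::as_tibble(raw)

  required <- c("product_id", "category", "sugars_g", "total_fat_g",
                "satfat_g", "salt_g", "protein_g")
  missing_cols <- setdiff(required, names(raw))
  if (!any(c("energy_kj", "energy_kcal") %in% names(raw))) {
    missing_cols <- c(missing_cols, "energy_kj|energy_kcal")
  }
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }

  df <- raw
  df$product_id <- as.character(df$product_id)
  df$category <- as.character(df$category)

  # energy: prefer the regulated unit (kJ); fall back to kcal x 4.184
  if (!"energy_kj" %in% names(df)) df$energy_kj <- NA_real_
  if ("energy_kcal" %in% names(df)) {
    from_kcal <- df$energy_kcal * 4.184
    both <- !is.na(df$energy_kj) & !is.na(df$energy_kcal)
    disagree <- both & abs(df$energy_kj - from_kcal) >
      0.02 * pmax(df$energy_kj, 1e-9)
    if (any(disagree)) {
      warning(sum(disagree), " row(s) declare inconsistent kJ/kcal ",
              "(>2% apart); keeping kJ", call. = FALSE)
    }
    df$energy_kj <- ifelse(is.na(df$energy_kj), from_kcal, df$energy_kj)
  }

  fiber_imputed <- if ("fiber_g" %in% names(df)) sum(is.na(df$fiber_g)) else
    nrow(df)
  if (!"fiber_g" %in% names(df)) df$fiber_g <- 0
  df$fiber_g[is.na(df$fiber_g)] <- 0

  fvl_defaulted <- if ("fvl_percent" %in% names(df))
    sum(is.na(df$fvl_percent)) else nrow(df)
  if (!"fvl_percent" %in% names(df)) df$fvl_percent <- 0
  df$fvl_percent[is.na(df$fvl_percent)] <- 0

  if (!"has_nns" %in% names(df)) {
    df$has_nns <- if ("ingredients_text" %in% names(df)) {
      vapply(df$ingredients_text,
             function(t) derive_flags(t)$has_nns, logical(1),
             USE.NAMES = FALSE)
    } else FALSE
  }
  df$has_nns <- as.logical(df$has_nns) %in% TRUE
  if (!"is_water" %in% names(df)) df$is_water <- FALSE
  df$is_water <- as.logical(df$is_water) %in% TRUE

  checks <- row_diagnostics(df)
  keep <- is.na(checks)
  rejected <- df[!keep, , drop = FALSE]
  rejected$reason <- checks[!keep]
  rejected$row <- which(!keep)

  products <- df[keep, , drop = FALSE]
  for (col in c("energy_kj", "sugars_g", "total_fat_g", "satfat_g", "salt_g",
                "protein_g", "fiber_g", "fvl_percent")) {
    products[[col]] <- as.numeric(products[[col]])
  }

  out <- list(
    products = products,
    rejected = rejected,
    fiber_imputed_count = fiber_imputed,
    fvl_defaulted_count = fvl_defaulted,
    provenance = path
  )
  class(out) <- "product_table"
  out
}

# per-row reason string, NA when the row is valid
row_diagnostics <- function(df) {
  n <- nrow(df)
  reason <- rep(NA_character_, n)
  note <- function(bad, msg) {
    bad <- which(bad & is.na(reason))
    reason[bad] <<- msg
  }
  num <- c("energy_kj", "sugars_g", "total_fat_g", "satfat_g", "salt_g",
           "protein_g", "fiber_g", "fvl_percent")
  for (col in num) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    note(is.na(v), paste0("non-numeric or missing ", col))
    note(!is.na(v) & v < 0, paste0("negative ", col))
  }
  note(!df$category %in% beverage_categories(), "unknown category")
  note(!is.na(df$satfat_g) & !is.na(df$total_fat_g) &
         df$satfat_g > df$total_fat_g, "saturated fat exceeds total fat")
  note(df$fvl_percent > 100, "fvl_percent above 100")
  note(duplicated(df$product_id), "duplicate product_id")
  reason
}

#' @export
print.product_table <- function(x, ...) {
  cat("<product_table> ", nrow(x$products), " products (",
      nrow(x$rejected), " rejected, ", x$fiber_imputed_count,
      " fiber values imputed to 0)\n", sep = "")
  cat("  source: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Derive ingredient-list flags
#'
#' Scans a free-text ingredient list for non-nutritive sweetener keywords
#' (case- and diacritic-insensitive; Spanish/English spellings and EU
#' E-numbers) and for an explicitly declared fruit/vegetable/legume
#' percentage such as "zumo de naranja (100%)".
#'
#' @param ingredients_text Character scalar (may be empty or `NA`).
#' @param keywords Character vector of sweetener keywords; defaults to the
#'   shipped keyword table.
#' @return A list with `has_nns` (logical) and `fvl_percent` (numeric or
#'   `NA` when no percentage is declared — the caller must then supply one).
#' @export
#' @examples
#' derive_flags("agua, edulcorantes: sucralosa, acesulfamo K")$has_nns
#' derive_flags("zumo de naranja (100%)")$fvl_percent
derive_flags <- function(ingredients_text, keywords = sweetener_keywords()) {
  if (length(ingredients_text) != 1) {
    stop("derive_flags() takes a single ingredient string", call. = FALSE)
  }
  if (is.na(ingredients_text) || !nzchar(trimws(ingredients_text))) {
    return(list(has_nns = FALSE, fvl_percent = NA_real_))
  }
  txt <- fold_text(ingredients_text)
  has_nns <- any(vapply(fold_text(keywords),
                        function(k) grepl(k, txt, fixed = TRUE), logical(1)))
  m <- regmatches(txt, regexpr("([0-9]+(\\.[0-9]+)?)[[:space:]]*%", txt))
  fvl <- if (length(m) == 1) as.numeric(sub("[[:space:]]*%", "", m)) else
    NA_real_
  if (!is.na(fvl) && (fvl < 0 || fvl > 100)) fvl <- NA_real_
  list(has_nns = has_nns, fvl_percent = fvl)
}

# lower-case + strip diacritics for keyword matching
fold_text <- function(x) {
  x <- tolower(x)
  out <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT")
  ifelse(is.na(out), x, out)
}

sweetener_keywords <- function() {
  path <- system.file("extdata", "config", "sweetener_keywords.json",
                      package = "bevscore", mustWork = TRUE)
  unlist(jsonlite::read_json(path)$keywords)
}

#' Write a scored product table to CSV
#'
#' Writes one row per product with the composition inputs, both versions'
#' totals and letters and the per-component points, in a stable column
#' order. The file round-trips exactly through [readr::read_csv()]:
#' write-read-write is byte-identical.
#'
#' @param scores Tibble from [score_products()] (with `version = "both"`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  need <- c("score_2015", "letter_2015", "score_2023", "letter_2023")
  missing_cols <- setdiff(need, names(scores))
  if (length(missing_cols) > 0) {
    stop("scores table lacks paired breakdown columns: ",
         paste(missing_cols, collapse = ", "),
         "; run score_products(version = 'both')", call. = FALSE)
  }
  first <- c("product_id", "category", "energy_kj", "sugars_g", "total_fat_g",
             "satfat_g", "salt_g", "protein_g", "fiber_g", "fvl_percent",
             "has_nns", "is_water", "scale_used_2015", "score_2015",
             "letter_2015", "scale_used_2023", "score_2023", "letter_2023")
  ordered <- c(intersect(first, names(scores)),
               sort(setdiff(names(scores), first)))
  readr::write_csv(scores[, ordered, drop = FALSE], path, progress = FALSE)
  invisible(path)
}
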