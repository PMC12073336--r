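#' Load a scoring scale
#'
#' Reads one of the shipped JSON scale definitions (point-band tables, letter
#' cut-offs and the water-only-A rule) and validates it. Three scales are
#' available: `"beverage_2015"` (original beverage algorithm),
#' `"food_2015"` (original general-food algorithm, applied to milk,
#' milkshakes and plant-based drinks under the 2015 rules) and
#' `"beverage_2023"` (updated beverage algorithm, all categories).
#'
#' @param name One of `"beverage_2015"`, `"food_2015"`, `"beverage_2023"`.
#' @param path Optional path to a custom scale JSON document with the same
#'   schema; overrides `name` lookup in the installed package.
#' @return An object of class `ns_scale`: a list with elements `name`,
#'   `version`, `water_only_A`, `components` (named list of band tables),
#'   `letters` (ordered letter/upper-score cut-offs) and `letter_top`.
#' @export
#' @examples
#' sc <- load_scale("beverage_2023")
#' theoretical_range(sc)
load_scale <- function(name = c("beverage_2015", "food_2015", "beverage_2023"),
                       path = NULL) {
  if (is.null(path)) {
    name <- match.arg(name)
    path <- system.file("extdata", "scales", paste0(name, ".json"),
                        package = "bevscore", mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  scale <- list(
    name = raw$name,
    version = raw$version,
    water_only_A = isTRUE(raw$water_only_A),
    components = lapply(raw$components, function(comp) {
      bands <- do.call(rbind, lapply(comp$bands, function(b) {
        c(threshold = as.numeric(b[[1]]), points = as.numeric(b[[2]]))
      }))
      list(
        polarity = comp$polarity,
        unit = comp$unit,
        thresholds = as.numeric(bands[, "threshold"]),
        points = as.integer(bands[, "points"]),
        top_points = as.integer(comp$top_points)
      )
    }),
    letters = do.call(rbind, lapply(raw$letters, function(l) {
      data.frame(letter = as.character(l[[1]]), upper = as.numeric(l[[2]]))
    })),
    letter_top = as.character(raw$letter_top)
  )
  class(scale) <- "ns_scale"
  validate_scale(scale)
  scale
}

validate_scale <- function(scale) {
  stopifnot(inherits(scale, "ns_scale"))
  if (length(scale$components) == 0L) {
    stop("scale '", scale$name, "' defines no components", call. = FALSE)
  }
  for (nm in names(scale$components)) {
    comp <- scale$components[[nm]]
    if (length(comp$thresholds) == 0L) {
      stop("component '", nm, "': empty band list", call. = FALSE)
    }
    if (is.unsorted(comp$thresholds, strictly = TRUE)) {
      stop("component '", nm, "': thresholds must be strictly increasing",
           call. = FALSE)
    }
    if (is.unsorted(comp$points)) {
      stop("component '", nm, "': points must be non-decreasing", call. = FALSE)
    }
    if (comp$top_points < comp$points[length(comp$points)]) {
      stop("component '", nm, "': top_points below the last band", call. = FALSE)
    }
    if (!comp$polarity %in% c("favorable", "unfavorable")) {
      stop("component '", nm, "': unknown polarity '", comp$polarity, "'",
           call. = FALSE)
    }
  }
  if (is.unsorted(scale$letters$upper, strictly = TRUE)) {
    stop("letter cut-offs must be strictly increasing", call. = FALSE)
  }
  invisible(scale)
}

#' @export
print.ns_scale <- function(x, ...) {
  rng <- theoretical_range(x)
  cat("<ns_scale> ", x$name, " (", x$version, ")\n", sep = "")
  cat("  components: ", paste(names(x$components), collapse = ", "), "\n",
      sep = "")
  cat("  score range: [", rng[1], ", ", rng[2], "]\n", sep = "")
  cat("  letters: ",
      paste0(x$letters$letter, " <= ", x$letters$upper, collapse = ", "),
      ", ", x$letter_top, " above",
      if (x$water_only_A) "; A reserved for water" else "", "\n", sep = "")
  invisible(x)
}

#' Points for one nutrient component
#'
#' Looks up the points awarded to a nutrient value in a point-band table.
#' Boundary semantics follow the label conventions: a value equal to a band's
#' upper threshold earns that band's points; a value strictly above the last
#' threshold earns the table's maximum.
#'
#' @param value Numeric vector of nutrient values (non-negative; percent for
#'   the fruit/vegetable/legume component).
#' @param table A component band table, e.g. `scale$components$sugars`.
#' @return Integer vector of points.
#' @export
#' @examples
#' sc15 <- load_scale("beverage_2015")
#' component_points(c(0, 271), sc15$components$energy) # 0 and 10
component_points <- function(value, table) {
  if (is.null(table$thresholds) || length(table$thresholds) == 0L) {
    stop("band table has no bands", call. = FALSE)
  }
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("component values must be finite and non-negative", call. = FALSE)
  }
  idx <- findInterval(value, table$thresholds, left.open = TRUE)
  pts <- c(table$points, table$top_points)[idx + 1L]
  as.integer(pts)
}

#' Points for the fruit/vegetable/legume percentage
#'
#' Step function over the declared percentage of fruits, vegetables, legumes
#' and qualifying oils (nut, rapeseed/canola, walnut, olive). Under the 2015
#' beverage bands the steps are 0/2/4/10 points at 40/60/80%; the 2015 food
#' bands award 0/1/2/5 and the 2023 beverage bands 0/2/4/6.
#'
#' @param percent Numeric vector in \[0, 100\].
#' @param scale An `ns_scale`.
#' @return Integer vector of points.
#' @export
#' @examples
#' fvl_points(c(40, 61, 81), load_scale("beverage_2023")) # 0, 4, 6
fvl_points <- function(percent, scale) {
  stopifnot(inherits(scale, "ns_scale"))
  if (any(!is.finite(percent)) || any(percent < 0 | percent > 100)) {
    stop("fvl percentage must lie in [0, 100]", call. = FALSE)
  }
  component_points(percent, scale$components$fvl)
}

#' Select the applicable 2015 scale for a category
#'
#' Under the original algorithm, plant-based beverages (cereal-, legume-,
#' nut-based and mixes), milk and milkshakes were scored as regular foods;
#' every other beverage category used the beverage bands.
#'
#' @param category Character vector of category identifiers
#'   (see [beverage_categories()]).
#' @return Character vector: `"food_2015"` or `"beverage_2015"` per element.
#' @export
#' @examples
#' select_scale_2015(c("milk", "sugar_sweetened"))
select_scale_2015 <- function(category) {
  bad <- setdiff(unique(category), beverage_categories())
  if (length(bad) > 0) {
    stop("unknown beverage category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ifelse(category %in% .FOOD_SCALE_2015_CATEGORIES, "food_2015",
         "beverage_2015")
}

#' Theoretical score range of a scale
#'
#' The minimum is the negated sum of the favorable component maxima; the
#' maximum is the sum of the unfavorable component maxima.
#'
#' @param scale An `ns_scale`.
#' @return Integer vector `c(min, max)`.
#' @export
#' @examples
#' theoretical_range(load_scale("beverage_2015")) # -20 40
#' theoretical_range(load_scale("beverage_2023")) # -18 54
theoretical_range <- function(scale) {
  stopifnot(inherits(scale, "ns_scale"))
  tops <- vapply(scale$components, function(c) c$top_points, integer(1))
  fav <- vapply(scale$components, function(c) c$polarity == "favorable",
                logical(1))
  c(-sum(tops[fav]), sum(tops[!fav]))
}

#' Letter grade for a total score
#'
#' Maps a total score to the five-level letter grade of the applicable scale.
#' On the beverage scales, A is reserved for plain/mineral water regardless of
#' score; every non-water beverage starts at B. The 2015 food scale assigns A
#' by score and ignores the water flag.
#'
#' @param score Integer vector of total scores, each within the scale's
#'   theoretical range.
#' @param scale An `ns_scale`.
#' @param is_water Logical vector (recycled): plain/mineral water flag.
#' @return Character vector of letters `"A"`..`"E"`.
#' @export
#' @examples
#' classify_score(c(1, 2, 11), load_scale("beverage_2015")) # "B" "C" "E"
classify_score <- function(score, scale, is_water = FALSE) {
  stopifnot(inherits(scale, "ns_scale"))
  rng <- theoretical_range(scale)
  if (any(!is.finite(score)) || any(score < rng[1] | score > rng[2])) {
    stop("score outside the theoretical range [", rng[1], ", ", rng[2], "]",
         call. = FALSE)
  }
  idx <- findInterval(score, scale$letters$upper, left.open = TRUE)
  letter <- c(scale$letters$letter, scale$letter_top)[idx + 1L]
  if (scale$water_only_A) {
    is_water <- rep_len(as.logical(is_water), length(score))
    letter[is_water] <- "A"
  }
  letter
}
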