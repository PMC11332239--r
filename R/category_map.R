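#' Named plumage colour categories
#'
#' The ten named categories used throughout the package, and the seven of
#' them for which a light/dark split is meaningful. White, black and yellow
#' are defined by lightness itself, so a light/dark split of those is not
#' meaningful.
#'
#' @name colour-categories
#' @keywords internal
NULL

PLUMAGE_CATEGORIES <- c("blue", "purple", "red", "yellow", "green",
                        "rufous", "brown", "grey", "white", "black")
SPLITTABLE_CATEGORIES <- c("blue", "brown", "green", "grey", "purple",
                           "red", "rufous")

# Rule-based classification of a single Lab point into a named category.
# Hue angle (degrees), chroma and lightness thresholds; the rules are a
# versioned, editable convention (the map can be replaced wholesale via CSV).
classify_lab <- function(L, a, b) {
  C <- sqrt(a^2 + b^2)
  h <- (atan2(b, a) * 180 / pi) %% 360
  if (C < 14) {
    if (L < 25) return("black")
    if (L > 75) return("white")
    return("grey")
  }
  if (h >= 70 && h < 110) {                    # yellow sector
    if (L >= 50 && C >= 30) return("yellow")
    return("brown")                            # dark/olive yellows read as brown
  }
  if (h >= 20 && h < 70) {                     # warm orange-red sector
    if (C >= 55) return("red")
    if (C >= 28) return("rufous")
    return("brown")
  }
  if (h >= 110 && h < 190) return("green")
  if (h >= 190 && h < 300) return("blue")
  if (h >= 300 && h < 340) return("purple")
  # h in [340, 360) or [0, 20): magenta-red wedge
  if (C >= 28) return("red")
  "rufous"
}

#' Default cell-to-category map
#'
#' Maps every cell of a Lab grid to one of the ten named plumage colour
#' categories, with a light/dark tone tag for the seven splittable colours
#' (blue, brown, green, grey, purple, red, rufous). Cells are classified by
#' rules on their centroid's hue angle `atan2(b, a)`, chroma
#' `sqrt(a^2 + b^2)` and lightness. Tone: the lower half of the L bins is
#' "dark", the upper half "light".
#'
#' @param grid A [lab_grid()].
#' @return A `category_map`: tibble with columns `a_bin`, `b_bin`, `L_bin`,
#'   `category`, `tone` (`"light"`, `"dark"`, or `NA` for black/white/yellow).
#' @examples
#' m <- default_category_map(lab_grid())
#' table(m$category)
#' @export
default_category_map <- function(grid = lab_grid()) {
  cc <- cell_centroids(grid)
  category <- mapply(classify_lab, cc$L, cc$a, cc$b)
  dark <- cc$L_bin <= grid$L_bins / 2
  tone <- ifelse(category %in% SPLITTABLE_CATEGORIES,
                 ifelse(dark, "dark", "light"), NA_character_)
  out <- tibble::tibble(
    a_bin = cc$a_bin, b_bin = cc$b_bin, L_bin = cc$L_bin,
    category = category, tone = tone
  )
  class(out) <- c("category_map", class(out))
  out
}

#' Read / write a category map as CSV
#'
#' The map is a plain CSV of `(a_bin, b_bin, L_bin, category, tone)` rows so
#' that alternative mappings can be versioned and audited.
#'
#' @param path File path.
#' @param map A `category_map` tibble.
#' @return `read_category_map()` returns a `category_map`;
#'   `write_category_map()` returns `path` invisibly.
#' @export
read_category_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  abort_if(!all(c("a_bin", "b_bin", "L_bin", "category") %in% names(df)),
           "category map CSV must have columns a_bin, b_bin, L_bin, category")
  if (is.null(df$tone)) df$tone <- NA_character_
  df$tone[df$tone %in% c("", "NA")] <- NA_character_
  out <- tibble::as_tibble(df)
  class(out) <- c("category_map", class(out))
  out
}

#' @rdname read_category_map
#' @export
write_category_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE, na = "")
  invisible(path)
}

# Check that a map covers every cell of a grid exactly once.
validate_category_map <- function(map, grid) {
  ids <- cell_id(map$a_bin, map$b_bin, map$L_bin, grid)
  abort_if(anyDuplicated(ids) > 0, "category map assigns some cell twice")
  missing <- setdiff(seq_len(n_cells(grid)), ids)
  abort_if(length(missing) > 0,
           sprintf("category map leaves %d cell(s) unmapped (first missing id %d)",
                   length(missing), missing[1]))
  bad <- setdiff(unique(map$category), PLUMAGE_CATEGORIES)
  abort_if(length(bad) > 0,
           paste("unknown categories in map:", paste(bad, collapse = ", ")))
  invisible(TRUE)
}
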