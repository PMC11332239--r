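#' Convert foreground pixels to CIELAB
#'
#' Converts the 8-bit sRGB foreground pixels of a plumage image to CIELAB
#' (D65 white point, via sRGB -> XYZ -> Lab).
#'
#' @param image A [plumage_image()], or an `n x 3` matrix of 0..255 sRGB
#'   values.
#' @return Numeric matrix with columns `L`, `a`, `b`, one row per foreground
#'   pixel.
#' @examples
#' rgb_to_lab(matrix(c(255, 255, 255), 1))  # L = 100, a ~ 0, b ~ 0
#' @export
rgb_to_lab <- function(image) {
  rgb <- if (inherits(image, "plumage_image")) foreground_rgb(image) else {
    abort_if(!is.matrix(image) || ncol(image) != 3,
             "image must be a plumage_image or an n x 3 sRGB matrix")
    image
  }
  lab <- farver::convert_colour(rgb, from = "rgb", to = "lab", white_to = "D65")
  colnames(lab) <- c("L", "a", "b")
  lab
}

#' Bin Lab pixels into a colour histogram
#'
#' Counts foreground pixels per cell of the Lab grid and converts the counts
#' to proportions. Occupied cells are the "colour loci". Cells with zero
#' pixels are omitted.
#'
#' @param lab An `n x 3` Lab matrix (columns L, a, b), or a
#'   [plumage_image()] (converted internally).
#' @param grid A [lab_grid()].
#' @return A `color_histogram`: tibble with columns `a_bin`, `b_bin`,
#'   `L_bin`, `count`, `prop`, carrying attributes `n_pixels`, `grid` and
#'   `n_clamped`.
#' @export
build_histogram <- function(lab, grid = lab_grid()) {
  if (inherits(lab, "plumage_image")) lab <- rgb_to_lab(lab)
  stopifnot(is.matrix(lab), ncol(lab) == 3)
  abort_if(nrow(lab) == 0, "no pixels to bin")
  bins <- lab_bin(lab, grid)
  id <- cell_id(bins$a_bin, bins$b_bin, bins$L_bin, grid)
  tab <- table(id)
  ids <- as.integer(names(tab))
  nab <- grid$a_bins * grid$b_bins
  hist <- tibble::tibble(
    a_bin = as.integer((ids - 1L) %% grid$a_bins + 1L),
    b_bin = as.integer(((ids - 1L) %/% grid$a_bins) %% grid$b_bins + 1L),
    L_bin = as.integer((ids - 1L) %/% nab + 1L),
    count = as.integer(tab),
    prop  = as.integer(tab) / nrow(lab)
  )
  attr(hist, "n_pixels") <- nrow(lab)
  attr(hist, "grid") <- grid
  attr(hist, "n_clamped") <- attr(bins, "n_clamped")
  class(hist) <- c("color_histogram", class(hist))
  hist
}

hist_grid <- function(hist) {
  g <- attr(hist, "grid")
  abort_if(is.null(g), "histogram carries no grid attribute")
  g
}

#' Aggregate a colour histogram to named category proportions
#'
#' Sums cell proportions by mapped category. The result is a full simplex
#' over the ten categories (absent categories get 0).
#'
#' @param hist A `color_histogram` from [build_histogram()].
#' @param map A `category_map`; default [default_category_map()] on the
#'   histogram's grid.
#' @return Named numeric vector over the ten categories, summing to 1.
#' @export
categorize <- function(hist, map = NULL) {
  grid <- hist_grid(hist)
  if (is.null(map)) map <- default_category_map(grid)
  validate_category_map(map, grid)
  key <- cell_id(map$a_bin, map$b_bin, map$L_bin, grid)
  hid <- cell_id(hist$a_bin, hist$b_bin, hist$L_bin, grid)
  pos <- match(hid, key)
  abort_if(anyNA(pos),
           sprintf("cell (%d,%d,%d) is not covered by the category map",
                   hist$a_bin[which(is.na(pos))[1]],
                   hist$b_bin[which(is.na(pos))[1]],
                   hist$L_bin[which(is.na(pos))[1]]))
  cats <- map$category[pos]
  out <- stats::setNames(numeric(length(PLUMAGE_CATEGORIES)), PLUMAGE_CATEGORIES)
  agg <- tapply(hist$prop, cats, sum)
  out[names(agg)] <- agg
  out
}

#' Light/dark sub-proportions for the splittable colours
#'
#' For each of blue, brown, green, grey, purple, red and rufous, returns the
#' proportion of foreground in the light and the dark form. Light + dark
#' reconstructs the category total exactly.
#'
#' @inheritParams categorize
#' @return A tibble with columns `category`, `light`, `dark`, `total`.
#' @export
split_light_dark <- function(hist, map = NULL) {
  grid <- hist_grid(hist)
  abort_if(grid$L_bins < 2, "light/dark split needs at least 2 L bins")
  if (is.null(map)) map <- default_category_map(grid)
  validate_category_map(map, grid)
  key <- cell_id(map$a_bin, map$b_bin, map$L_bin, grid)
  pos <- match(cell_id(hist$a_bin, hist$b_bin, hist$L_bin, grid), key)
  df <- tibble::tibble(category = map$category[pos], tone = map$tone[pos],
                       prop = hist$prop)
  out <- tibble::tibble(category = SPLITTABLE_CATEGORIES, light = 0, dark = 0)
  for (i in seq_len(nrow(out))) {
    sel <- df$category == out$category[i]
    out$light[i] <- sum(df$prop[sel & df$tone == "light"])
    out$dark[i]  <- sum(df$prop[sel & df$tone == "dark"])
  }
  out$total <- out$light + out$dark
  out
}

#' Colour diversity: number of occupied colour loci
#'
#' @param hist A `color_histogram`.
#' @param min_prop Minimum proportion for a cell to count as occupied
#'   (default 0: any cell with at least one pixel counts). A small positive
#'   value suppresses anti-aliasing speckle.
#' @return Integer count of occupied cells.
#' @export
colour_diversity <- function(hist, min_prop = 0) {
  sum(hist$prop > min_prop)
}

#' Global average colour across a species panel
#'
#' The proportion-weighted mean Lab colour of each species x sex unit,
#' averaged (unweighted) across units. Empirically a brown-grey for realistic
#' bird panels.
#'
#' @param hists List of `color_histogram` objects (one per species x sex).
#' @return Numeric length-3 vector `c(L, a, b)`.
#' @export
global_mean_colour <- function(hists) {
  abort_if(length(hists) == 0, "need at least one histogram")
  means <- vapply(hists, function(h) {
    cc <- hist_centroids(h)
    c(sum(h$prop * cc$L), sum(h$prop * cc$a), sum(h$prop * cc$b))
  }, numeric(3))
  stats::setNames(rowMeans(means), c("L", "a", "b"))
}

hist_centroids <- function(hist) {
  grid <- hist_grid(hist)
  mid <- function(br) (br[-1] + br[-length(br)]) / 2
  tibble::tibble(
    L = mid(grid$L_breaks)[hist$L_bin],
    a = mid(grid$a_breaks)[hist$a_bin],
    b = mid(grid$b_breaks)[hist$b_bin]
  )
}

#' Colour elaboration: mean distance from the global average colour
#'
#' The proportion-weighted mean Euclidean CIELAB distance (Delta E*ab)
#' between a unit's colours (occupied cell centroids) and the global average
#' colour of the panel. Zero iff all colour mass sits at the global mean;
#' larger values indicate colours departing from the panel-average
#' brown-grey.
#'
#' @param hist A `color_histogram`.
#' @param global_mean Length-3 `c(L, a, b)` from [global_mean_colour()].
#' @param weighted If `TRUE` (default) cells are weighted by their pixel
#'   proportion; if `FALSE` all occupied cells weigh equally.
#' @return Non-negative Delta E value.
#' @export
colour_elaboration <- function(hist, global_mean, weighted = TRUE) {
  abort_if(is.null(global_mean) || length(global_mean) != 3,
           "global mean colour must be computed first (length-3 Lab vector)")
  cc <- hist_centroids(hist)
  d <- sqrt((cc$L - global_mean[1])^2 + (cc$a - global_mean[2])^2 +
            (cc$b - global_mean[3])^2)
  if (weighted) sum(hist$prop * d) else mean(d)
}

#' Full colour profile for a panel of plumage images
#'
#' Runs the complete colour pipeline for a list of images: CIELAB
#' conversion, grid binning, category aggregation with light/dark forms,
#' colour diversity and colour elaboration (against the panel-wide global
#' mean colour).
#'
#' @param images Named list of [plumage_image()] objects (names identify the
#'   species x sex unit).
#' @param grid A [lab_grid()].
#' @param map A `category_map` (default rule-based map on `grid`).
#' @param min_prop Occupancy threshold passed to [colour_diversity()].
#' @return A tibble with one row per image: `unit`, the ten category
#'   proportions, `light_*`/`dark_*` for the seven splittable colours,
#'   `loci` (colour diversity) and `elaboration`. The attribute
#'   `global_mean` stores the panel mean colour; `histograms` the per-unit
#'   histograms.
#' @export
color_profile <- function(images, grid = lab_grid(), map = NULL,
                          min_prop = 0) {
  abort_if(length(images) == 0, "no images supplied")
  if (is.null(names(images))) names(images) <- sprintf("unit_%03d", seq_along(images))
  if (is.null(map)) map <- default_category_map(grid)
  hists <- lapply(images, function(im) build_histogram(rgb_to_lab(im), grid))
  gm <- global_mean_colour(hists)
  rows <- lapply(names(hists), function(nm) {
    h <- hists[[nm]]
    cats <- categorize(h, map)
    ld <- split_light_dark(h, map)
    row <- c(as.list(cats),
             stats::setNames(as.list(ld$light), paste0("light_", ld$category)),
             stats::setNames(as.list(ld$dark), paste0("dark_", ld$category)))
    tibble::tibble(unit = nm, !!!row,
                   loci = colour_diversity(h, min_prop),
                   elaboration = colour_elaboration(h, gm))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "global_mean") <- gm
  attr(out, "histograms") <- hists
  out
}
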