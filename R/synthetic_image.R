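#' Representative sRGB colours for each named category
#'
#' For every category (optionally split by tone) selects one grid cell whose
#' centroid survives the Lab -> 8-bit sRGB -> Lab round trip inside the same
#' cell, guaranteeing that pixels painted with the returned colour land in a
#' cell of the intended category despite gamut clipping and quantisation.
#' Among the valid cells the one with the smallest round-trip Delta E is
#' chosen (ties by cell index), so the choice is deterministic.
#'
#' @param grid A [lab_grid()].
#' @param map A `category_map` (default rule-based map).
#' @return A tibble with columns `key` (category or `tone_category`),
#'   `category`, `tone`, the cell indices, the sRGB triple `R`, `G`, `B` and
#'   the post-quantisation Lab coordinates.
#' @export
category_colors <- function(grid = lab_grid(), map = NULL) {
  if (is.null(map)) map <- default_category_map(grid)
  validate_category_map(map, grid)
  cc <- cell_centroids(grid)
  srgb <- farver::convert_colour(as.matrix(cc[, c("L", "a", "b")]),
                                 from = "lab", to = "rgb", white_from = "D65")
  srgb <- round(clamp(srgb, 0, 255))
  back <- farver::convert_colour(srgb, from = "rgb", to = "lab", white_to = "D65")
  rebin <- lab_bin(back, grid)
  same_cell <- rebin$a_bin == cc$a_bin & rebin$b_bin == cc$b_bin &
    rebin$L_bin == cc$L_bin
  err <- sqrt(rowSums((back - as.matrix(cc[, c("L", "a", "b")]))^2))

  pick <- function(sel) {
    sel <- which(sel & same_cell)
    if (length(sel) == 0) return(NULL)
    sel[which.min(err[sel])]
  }
  keys <- c(PLUMAGE_CATEGORIES,
            paste0("light_", SPLITTABLE_CATEGORIES),
            paste0("dark_", SPLITTABLE_CATEGORIES))
  rows <- list()
  for (k in keys) {
    if (grepl("^(light|dark)_", k)) {
      tone <- sub("_.*$", "", k)
      cat <- sub("^(light|dark)_", "", k)
      i <- pick(map$category == cat & !is.na(map$tone) & map$tone == tone)
    } else {
      tone <- NA_character_; cat <- k
      i <- pick(map$category == k)
    }
    if (is.null(i)) next
    rows[[k]] <- tibble::tibble(
      key = k, category = cat, tone = tone,
      a_bin = cc$a_bin[i], b_bin = cc$b_bin[i], L_bin = cc$L_bin[i],
      R = srgb[i, 1], G = srgb[i, 2], B = srgb[i, 3],
      L = back[i, 1], a = back[i, 2], b = back[i, 3]
    )
  }
  dplyr::bind_rows(rows)
}

#' Generate a plumage image with known colour composition
#'
#' Paints a synthetic "illustration" whose foreground pixels are split across
#' named colour categories in requested proportions, using representative
#' colours verified to land in cells of those categories. Ground truth (the
#' exact expected colour histogram, computed from the emitted pixel values)
#' is attached, so the colour pipeline has an exact round-trip oracle.
#'
#' @param mix Named numeric vector over category keys (e.g. `c(red = 0.5,
#'   black = 0.5)`, tone-specific keys like `"light_blue"` allowed), summing
#'   to 1. Pixel counts are apportioned by largest remainder, so realised
#'   counts match the mix within one pixel.
#' @param layout `"stripe"` (full-frame horizontal bands) or `"blob"`
#'   (elliptical bird-ish foreground on transparent background).
#' @param size Image side in pixels (square), default 32.
#' @param seed Integer seed (stream independent of taxonomy/ratings).
#' @param grid,map Grid and category map used to pick representative colours.
#' @param palette Optional precomputed [category_colors()] table (saves
#'   recomputation across many images).
#' @return A [plumage_image()] with attributes `expected_histogram` (a
#'   `color_histogram`), `expected_mix` (realised per-key pixel proportions)
#'   and `expected_diversity`.
#' @export
generate_plumage_image <- function(mix, layout = c("stripe", "blob"),
                                   size = 32, seed = 1L,
                                   grid = lab_grid(), map = NULL,
                                   palette = NULL) {
  layout <- match.arg(layout)
  abort_if(length(mix) == 0 || is.null(names(mix)), "mix must be a named vector")
  abort_if(any(mix < 0) || abs(sum(mix) - 1) > 1e-9, "mix must be a simplex")
  if (is.null(palette)) palette <- category_colors(grid, map)
  unknown <- setdiff(names(mix), palette$key)
  abort_if(length(unknown) > 0,
           paste("unknown colour categories in mix:", paste(unknown, collapse = ", ")))
  set.seed(sub_seed(seed, "image"))

  h <- size; w <- size
  mask <- if (layout == "blob") {
    yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    ((yy - (h + 1) / 2) / (0.45 * h))^2 + ((xx - (w + 1) / 2) / (0.45 * w))^2 <= 1
  } else {
    matrix(TRUE, h, w)
  }
  fg <- which(mask)                     # column-major order -> vertical bands;
  fg <- fg[order((fg - 1) %% h)]        # reorder row-major -> horizontal bands
  n_fg <- length(fg)
  counts <- apportion(n_fg, mix[mix > 0])

  rgb <- array(180L, dim = c(h, w, 3))  # neutral grey background
  pal <- palette[match(names(counts), palette$key), ]
  at <- 1L
  for (i in seq_along(counts)) {
    if (counts[i] == 0) next
    px <- fg[at:(at + counts[i] - 1L)]
    rgb[, , 1][px] <- pal$R[i]; rgb[, , 2][px] <- pal$G[i]; rgb[, , 3][px] <- pal$B[i]
    at <- at + counts[i]
  }
  img <- plumage_image(rgb, mask)

  # expected histogram: bin the emitted representative colours directly
  occupied <- counts > 0
  eh <- tibble::tibble(a_bin = pal$a_bin[occupied], b_bin = pal$b_bin[occupied],
                       L_bin = pal$L_bin[occupied],
                       count = as.integer(counts[occupied]))
  eh <- dplyr::summarise(dplyr::group_by(eh, .data$a_bin, .data$b_bin, .data$L_bin),
                         count = sum(.data$count), .groups = "drop")
  eh <- dplyr::arrange(eh, .data$L_bin, .data$b_bin, .data$a_bin)
  eh$prop <- eh$count / n_fg
  attr(eh, "n_pixels") <- n_fg
  attr(eh, "grid") <- grid
  attr(eh, "n_clamped") <- 0L
  class(eh) <- c("color_histogram", class(eh))

  attr(img, "expected_histogram") <- eh
  attr(img, "expected_mix") <- counts / n_fg
  attr(img, "expected_diversity") <- nrow(eh)
  img
}
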