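#' Define the CIELAB binning grid
#'
#' The grid discretises CIELAB space into `a_bins` x `b_bins` x `L_bins`
#' rectangular cells ("colour loci"). The default 12 x 12 x 4 grid yields 576
#' cells. Bins are half-open `[lo, hi)` except the last bin on each axis,
#' which is closed, so every in-range value falls in exactly one cell.
#' Values outside the chromatic ranges are clamped into the edge bins (the
#' sRGB gamut is comfortably inside the default a, b range of -110..110).
#'
#' @param a_bins,b_bins Number of bins on the chromatic a (green-red) and
#'   b (blue-yellow) axes. Default 12.
#' @param L_bins Number of bins on the achromatic lightness axis. Default 4.
#' @param a_range,b_range Numeric length-2 chromatic bounds. Default
#'   `c(-110, 110)`.
#' @param L_range Lightness bounds, default `c(0, 100)`.
#' @return An object of class `lab_grid`.
#' @examples
#' g <- lab_grid()
#' n_cells(g)  # 576
#' @export
lab_grid <- function(a_bins = 12, b_bins = 12, L_bins = 4,
                     a_range = c(-110, 110), b_range = c(-110, 110),
                     L_range = c(0, 100)) {
  abort_if(a_bins < 1 || b_bins < 1 || L_bins < 1,
           "all bin counts must be >= 1")
  abort_if(diff(a_range) <= 0 || diff(b_range) <= 0 || diff(L_range) <= 0,
           "axis ranges must be increasing")
  structure(
    list(
      a_bins = as.integer(a_bins), b_bins = as.integer(b_bins),
      L_bins = as.integer(L_bins),
      a_breaks = seq(a_range[1], a_range[2], length.out = a_bins + 1),
      b_breaks = seq(b_range[1], b_range[2], length.out = b_bins + 1),
      L_breaks = seq(L_range[1], L_range[2], length.out = L_bins + 1)
    ),
    class = "lab_grid"
  )
}

#' Total number of cells in a Lab grid
#' @param grid A [lab_grid()].
#' @return Integer cell count.
#' @export
n_cells <- function(grid) {
  stopifnot(inherits(grid, "lab_grid"))
  grid$a_bins * grid$b_bins * grid$L_bins
}

#' @export
print.lab_grid <- function(x, ...) {
  cat(sprintf("CIELAB grid: %d a-bins x %d b-bins x %d L-bins = %d cells\n",
              x$a_bins, x$b_bins, x$L_bins, n_cells(x)))
  cat(sprintf("  a in [%g, %g], b in [%g, %g], L in [%g, %g]\n",
              min(x$a_breaks), max(x$a_breaks),
              min(x$b_breaks), max(x$b_breaks),
              min(x$L_breaks), max(x$L_breaks)))
  invisible(x)
}

# Bin index on one axis: half-open [lo, hi), last bin closed; out-of-range
# values clamp to the edge bins.
axis_bin <- function(x, breaks) {
  findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Assign Lab pixels to grid cells
#'
#' @param lab Numeric matrix with columns L, a, b (one pixel per row).
#' @param grid A [lab_grid()].
#' @return A tibble with integer columns `a_bin`, `b_bin`, `L_bin` (1-based),
#'   one row per pixel. The attribute `n_clamped` counts pixels that fell
#'   outside the grid ranges and were clamped to edge bins.
#' @export
lab_bin <- function(lab, grid) {
  stopifnot(inherits(grid, "lab_grid"), is.matrix(lab), ncol(lab) == 3)
  L <- lab[, 1]; a <- lab[, 2]; b <- lab[, 3]
  out_of_range <- sum(
    a < min(grid$a_breaks) | a > max(grid$a_breaks) |
    b < min(grid$b_breaks) | b > max(grid$b_breaks) |
    L < min(grid$L_breaks) | L > max(grid$L_breaks)
  )
  res <- tibble::tibble(
    a_bin = axis_bin(a, grid$a_breaks),
    b_bin = axis_bin(b, grid$b_breaks),
    L_bin = axis_bin(L, grid$L_breaks)
  )
  attr(res, "n_clamped") <- out_of_range
  if (out_of_range > 0) {
    message(sprintf("lab_bin: %d pixel(s) outside grid range clamped to edge bins",
                    out_of_range))
  }
  res
}

#' Centroids of all grid cells
#'
#' @param grid A [lab_grid()].
#' @return A tibble with one row per cell: `a_bin`, `b_bin`, `L_bin`, and the
#'   centroid coordinates `L`, `a`, `b`.
#' @export
cell_centroids <- function(grid) {
  stopifnot(inherits(grid, "lab_grid"))
  mid <- function(br) (br[-1] + br[-length(br)]) / 2
  cells <- expand.grid(
    a_bin = seq_len(grid$a_bins),
    b_bin = seq_len(grid$b_bins),
    L_bin = seq_len(grid$L_bins),
    KEEP.OUT.ATTRS = FALSE
  )
  tibble::tibble(
    a_bin = cells$a_bin, b_bin = cells$b_bin, L_bin = cells$L_bin,
    L = mid(grid$L_breaks)[cells$L_bin],
    a = mid(grid$a_breaks)[cells$a_bin],
    b = mid(grid$b_breaks)[cells$b_bin]
  )
}

# Single linear cell id (1-based) from bin triples; used internally for
# tabulation and joins.
cell_id <- function(a_bin, b_bin, L_bin, grid) {
  (L_bin - 1L) * grid$a_bins * grid$b_bins + (b_bin - 1L) * grid$a_bins + a_bin
}
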