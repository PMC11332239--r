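#' Construct a plumage image
#'
#' A `plumage_image` is an 8-bit sRGB raster plus a logical foreground mask:
#' one illustrated bird (a species x sex unit). Background pixels (mask
#' `FALSE`) are ignored by all colour quantification.
#'
#' @param rgb Integer array `h x w x 3` with values in 0..255.
#' @param mask Logical `h x w` matrix; `TRUE` marks foreground (the bird).
#'   Default: all pixels are foreground.
#' @return An object of class `plumage_image`.
#' @export
plumage_image <- function(rgb, mask = NULL) {
  abort_if(length(dim(rgb)) != 3 || dim(rgb)[3] != 3,
           "rgb must be an h x w x 3 array")
  abort_if(min(rgb) < 0 || max(rgb) > 255, "rgb values must lie in 0..255")
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  abort_if(!is.logical(mask) || !all(dim(mask) == c(h, w)),
           "mask must be a logical h x w matrix")
  structure(list(rgb = array(as.integer(round(rgb)), dim = c(h, w, 3)),
                 mask = mask),
            class = "plumage_image")
}

#' @export
print.plumage_image <- function(x, ...) {
  cat(sprintf("plumage_image: %d x %d px, %d foreground (%.1f%%)\n",
              dim(x$rgb)[1], dim(x$rgb)[2], sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' Read / write a plumage image as PNG
#'
#' Images are stored as 8-bit RGBA PNG; the alpha channel carries the
#' foreground mask (255 = foreground, 0 = background).
#'
#' @param path File path.
#' @param image A [plumage_image()].
#' @return `read_plumage_png()` returns a `plumage_image`;
#'   `write_plumage_png()` returns `path` invisibly.
#' @export
read_plumage_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  rgb <- round(arr[, , 1:3, drop = FALSE] * 255)
  mask <- if (dim(arr)[3] >= 4) arr[, , 4] > 0.5 else NULL
  plumage_image(rgb, mask)
}

#' @rdname read_plumage_png
#' @export
write_plumage_png <- function(image, path) {
  stopifnot(inherits(image, "plumage_image"))
  h <- dim(image$rgb)[1]; w <- dim(image$rgb)[2]
  arr <- array(0, dim = c(h, w, 4))
  arr[, , 1:3] <- image$rgb / 255
  arr[, , 4] <- ifelse(image$mask, 1, 0)
  png::writePNG(arr, path)
  invisible(path)
}

# Foreground pixels as an n x 3 integer matrix (R, G, B), row-major over the
# image in column order (order is irrelevant downstream: all outputs are
# permutation invariant).
foreground_rgb <- function(image) {
  stopifnot(inherits(image, "plumage_image"))
  idx <- which(image$mask)
  abort_if(length(idx) == 0, "image has no foreground pixel")
  cbind(image$rgb[, , 1][idx], image$rgb[, , 2][idx], image$rgb[, , 3][idx])
}
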