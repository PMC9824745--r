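#' Grayscale micrograph with a physical pixel scale
#'
#' Light container binding an 8-bit intensity matrix to the physical size of
#' one pixel. All downstream stages (segmentation, morphometry, region-of-
#' interest analysis) consume and produce this class, so calibration travels
#' with the pixels.
#'
#' Conventions: `pixels[row, col]` holds intensities in `[0, 255]` (integers;
#' values are rounded on construction). Pixel coordinates are 0-based and
#' refer to pixel centers; the physical position of pixel `(row, col)` is
#' `(col * nm_per_px, row * nm_per_px)` nanometres from the top-left pixel
#' center, x increasing along columns.
#'
#' @param pixels Numeric matrix of intensities in `[0, 255]`.
#' @param nm_per_px Physical size of one pixel in nanometres (> 0).
#' @param source_id Free-text identifier carried into particle tables.
#'
#' @return An object of class `image_grid`.
#' @examples
#' img <- image_grid(matrix(200, 64, 64), nm_per_px = 0.5)
#' dim(img$pixels)
#' @export
image_grid <- function(pixels, nm_per_px, source_id = "image") {
  if (!is.matrix(pixels) || nrow(pixels) < 1 || ncol(pixels) < 1)
    abort("`pixels` must be a non-empty matrix")
  if (!is.numeric(nm_per_px) || length(nm_per_px) != 1 || nm_per_px <= 0)
    abort("`nm_per_px` must be a single positive number")
  px <- round(pixels)
  if (anyNA(px) || min(px) < 0 || max(px) > 255)
    abort("intensities must lie in [0, 255]")
  storage.mode(px) <- "integer"
  structure(
    list(pixels = px, nm_per_px = as.numeric(nm_per_px),
         source_id = as.character(source_id)),
    class = "image_grid"
  )
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d px, %.4g nm/px, source '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$nm_per_px, x$source_id))
  invisible(x)
}

#' @export
dim.image_grid <- function(x) dim(x$pixels)

is_image_grid <- function(x) inherits(x, "image_grid")

assert_image_grid <- function(x) {
  if (!is_image_grid(x)) abort("expected an `image_grid` object")
  invisible(x)
}
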