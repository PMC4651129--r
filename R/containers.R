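#' Spot image container
#'
#' An RGB raster of one TMA spot (a circular tissue core section) together
#' with its physical pixel size and the validity region: the spot perimeter is
#' delineated and pixels exterior to it are excluded from all analyses.
#'
#' @param pixels H x W x 3 array, 8-bit RGB values in `[0, 255]`.
#' @param pixel_size_um Positive real; physical size of one pixel in microns.
#' @param inside_spot H x W logical matrix; `TRUE` for pixels inside the spot
#'   perimeter.
#' @return Object of class `spot_image`.
#' @export
spot_image <- function(pixels, pixel_size_um, inside_spot) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L,
            is.matrix(inside_spot), is.logical(inside_spot),
            all(dim(pixels)[1:2] == dim(inside_spot)),
            is.numeric(pixel_size_um), pixel_size_um > 0)
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in [0, 255]")
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um),
                 inside_spot = inside_spot),
            class = "spot_image")
}

#' @export
print.spot_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("spot_image: %d x %d px, %.3g um/px, %d px inside spot\n",
              d[1], d[2], x$pixel_size_um, sum(x$inside_spot)))
  invisible(x)
}

#' Label mask container
#'
#' Per-pixel tumour/non-tumour labels for one spot, the unit of comparison
#' between pathologists and the automated segmenter. Encoding: 0 = OUTSIDE
#' (beyond the spot perimeter), 1 = N (non-tumour), 2 = T (tumour).
#'
#' @param labels Integer matrix with values in `{0, 1, 2}`.
#' @return Object of class `label_mask` (an integer matrix).
#' @export
label_mask <- function(labels) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), c(0L, 1L, 2L))
  if (length(bad) > 0) {
    stop("mask contains labels outside {0, 1, 2}: ", paste(bad, collapse = ", "))
  }
  structure(labels, class = c("label_mask", "matrix", "array"))
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("label_mask: %d x %d px (%d OUTSIDE, %d N, %d T)\n",
              nrow(x), ncol(x), sum(x == 0L), sum(x == 1L), sum(x == 2L)))
  invisible(x)
}

# Strip the class so base matrix ops behave predictably internally.
mask_matrix <- function(mask) {
  m <- unclass(mask)
  attr(m, "class") <- NULL
  m
}

# Check two masks cover the same spot (shape and OUTSIDE set agree).
check_comparable <- function(maskA, maskB) {
  if (!all(dim(maskA) == dim(maskB))) {
    stop("masks have different shapes")
  }
  if (!identical(unclass(maskA) == 0L, unclass(maskB) == 0L)) {
    stop("masks have different OUTSIDE sets; spot perimeters must agree")
  }
  invisible(TRUE)
}
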