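#' Grayscale image container
#'
#' A `gray_image` holds a single-channel intensity raster in floating point
#' on \[0, 1\], together with the dynamic range `L` of the source (256 for
#' 8-bit input, 65536 for 16-bit) kept as metadata, and an origin label.
#' All processing in this package operates on the normalized \[0, 1\] scale;
#' `L` is consulted only where the dynamic range matters (quantization on
#' write, metric reporting scale).
#'
#' Pixel (1, 1) is the top-left corner; indexing is row-major `(row, column)`
#' throughout the package.
#'
#' @param pixels Numeric matrix (rows x cols) of finite intensities.
#' @param L Dynamic range of the source image (positive; default 256).
#' @param origin Character label identifying the source (file path or
#'   `"synthetic"`).
#' @param normalize If `TRUE` (default) and `pixels` exceeds \[0, 1\], values
#'   are clipped into range; `FALSE` keeps out-of-range values as-is (used
#'   for signed intermediate results such as transform reconstructions).
#'
#' @return An object of class `gray_image`: a list with elements `pixels`,
#'   `L` and `origin`.
#' @export
#' @examples
#' img <- gray_image(matrix(runif(64), 8))
#' dim(img)
gray_image <- function(pixels, L = 256, origin = "synthetic", normalize = TRUE) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix (single-channel image)", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("image contains non-finite pixel values", call. = FALSE)
  if (!is.numeric(L) || length(L) != 1L || L <= 0)
    stop("`L` must be a single positive number", call. = FALSE)
  if (normalize) pixels <- clip01(pixels)
  structure(list(pixels = pixels, L = L, origin = as.character(origin)[1]),
            class = "gray_image")
}

#' Coerce to a gray_image
#'
#' Matrices are wrapped (clipping into \[0, 1\] if necessary); `gray_image`
#' objects pass through unchanged.
#'
#' @param x A numeric matrix or `gray_image`.
#' @param ... Passed on to [gray_image()] for matrix input.
#' @return A `gray_image`.
#' @export
as_gray_image <- function(x, ...) {
  if (inherits(x, "gray_image")) return(x)
  gray_image(x, ...)
}

#' Extract the pixel matrix of an image
#'
#' @param x A `gray_image` or numeric matrix.
#' @return The numeric pixel matrix.
#' @export
pixels <- function(x) {
  if (inherits(x, "gray_image")) x$pixels else if (is.matrix(x)) x
  else stop("expected a gray_image or a numeric matrix", call. = FALSE)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @export
print.gray_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<gray_image> %d x %d, L = %g, origin = %s\n", d[1], d[2], x$L, x$origin))
  cat(sprintf("  intensity range [%.4g, %.4g], mean %.4g\n",
              min(x$pixels), max(x$pixels), mean(x$pixels)))
  invisible(x)
}

# clamp values into [0, 1]
clip01 <- function(x) pmin(pmax(x, 0), 1)

# rebuild an image around a new pixel matrix, keeping metadata
with_pixels <- function(img, px) {
  if (inherits(img, "gray_image")) {
    img$pixels <- px
    img
  } else px
}
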