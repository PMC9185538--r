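#' Read a grayscale PNG or TIFF image
#'
#' Reads an 8-bit or 16-bit single-channel PNG or TIFF file into a
#' [gray_image()] normalized to \[0, 1\]. The dynamic range `L` is recorded
#' from the file's bit depth (256 or 65536). Multi-channel images are
#' rejected unless all channels are identical (a gray image stored as RGB),
#' in which case the first channel is taken; true color input must be
#' converted explicitly by the caller — silent luminance conversion hides
#' data problems in radiographs, which are single-channel by nature.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A `gray_image` with pixels in \[0, 1\] and `L` set from the bit
#'   depth.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    bits <- png_bit_depth(path)
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(arr, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
  } else {
    stop("unsupported image format '", ext, "': expected PNG or TIFF", call. = FALSE)
  }
  px <- collapse_channels(arr, path)
  gray_image(px, L = 2^bits, origin = path)
}

#' Write a gray_image to disk
#'
#' Quantizes the \[0, 1\] intensities to `bits` bits with the fixed rounding
#' rule `floor(v * (2^bits - 1) + 0.5)` (round half up) and writes a PNG or
#' TIFF depending on the file extension. Read-back error is at most half a
#' quantization step, `1 / (2 * (2^bits - 1))`, per pixel. 16-bit output is
#' available for TIFF; the PNG writer used here is 8-bit only.
#'
#' @param img A `gray_image` or numeric matrix (values clipped to \[0, 1\]).
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @param bits Output bit depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path, bits = 8L) {
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L)) stop("`bits` must be 8 or 16", call. = FALSE)
  px <- clip01(pixels(img))
  maxv <- 2^bits - 1
  q <- floor(px * maxv + 0.5) / maxv  # fixed rounding rule: half rounds up
  ext <- tolower(tools::file_ext(path))
  ok <- if (ext == "png") {
    if (bits == 16L)
      stop("16-bit PNG output is not supported; write a TIFF instead", call. = FALSE)
    try(png::writePNG(q, path), silent = TRUE)
  } else if (ext %in% c("tif", "tiff")) {
    try(tiff::writeTIFF(q, path, bits.per.sample = bits), silent = TRUE)
  } else {
    stop("unsupported output format '", ext, "'", call. = FALSE)
  }
  if (inherits(ok, "try-error"))
    stop("could not write image to ", path, call. = FALSE)
  invisible(path)
}

# PNG bit depth lives at byte 25 of the file (IHDR chunk); the reader
# package normalizes intensities without exposing it.
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 26L) stop("truncated PNG file: ", path, call. = FALSE)
  as.integer(hdr[25L])
}

# Accept (M,N) matrices or (M,N,k) arrays whose channels are identical.
collapse_channels <- function(arr, path) {
  if (is.matrix(arr)) return(arr[, , drop = TRUE])
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    ch1 <- arr[, , 1]
    # alpha (2- or 4-channel) and duplicated-gray RGB are collapsible
    color <- if (nch >= 3) 2:3 else integer(0)
    for (k in color) {
      if (max(abs(arr[, , k] - ch1)) > 0)
        stop("multi-channel (color) image not supported: ", path,
             "; convert to single-channel grayscale first", call. = FALSE)
    }
    return(ch1)
  }
  stop("unsupported image array layout in ", path, call. = FALSE)
}

#' Histogram equalization
#'
#' Standard cumulative-distribution remapping: intensities are binned into
#' `n_bins` equal-width bins on \[0, 1\] and each pixel is mapped to the
#' cumulative probability of its bin. The mapping is monotone non-decreasing
#' in input intensity, so pixel rank order is preserved. A constant image
#' (single occupied bin) is returned unchanged — the degenerate case is
#' defined so downstream stages never divide by zero.
#'
#' @param img A `gray_image` or matrix with values in \[0, 1\].
#' @param n_bins Number of histogram bins (default 256, the 8-bit
#'   convention, regardless of the source bit depth).
#' @return Image of the same type and shape with equalized intensities.
#' @export
histogram_equalize <- function(img, n_bins = 256L) {
  px <- pixels(img)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("`n_bins` must be at least 2", call. = FALSE)
  lev <- quantize_levels(px, n_bins)
  counts <- tabulate(lev + 1L, nbins = n_bins)
  if (sum(counts > 0L) <= 1L) return(img)  # constant image: identity
  cdf <- cumsum(counts) / length(px)
  out <- matrix(cdf[lev + 1L], nrow(px), ncol(px))
  with_pixels(img, out)
}

#' Linear grayscale stretch
#'
#' Affine map of `[min, max]` onto \[0, 1\]. Used for displaying detail
#' sub-bands, whose signed values have no natural display range. A constant
#' image maps to all zeros (documented convention).
#'
#' @param img A `gray_image` or numeric matrix.
#' @return Same type and shape, spanning \[0, 1\] for non-constant input.
#' @export
linear_stretch <- function(img) {
  px <- pixels(img)
  rng <- range(px)
  out <- if (rng[2] > rng[1]) (px - rng[1]) / (rng[2] - rng[1])
         else matrix(0, nrow(px), ncol(px))
  with_pixels(img, out)
}

# map [0,1] values onto integer levels 0..n-1 (level k covers [k/n,(k+1)/n),
# top edge closed)
quantize_levels <- function(px, n) {
  pmin(floor(px * n), n - 1L)
}
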