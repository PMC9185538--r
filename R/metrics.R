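# No-reference quality metrics. All four are computed on intensities
# rescaled to the 0..255 convention by default (scale = 255), the scale on
# which published AG/SF/EI magnitudes for radiographs are quoted; pass
# scale = 1 for native normalized units.

#' Average gradient (AG)
#'
#' Mean magnitude of the forward intensity differences,
#' `sqrt((f(i,j) - f(i+1,j))^2 + (f(i,j) - f(i,j+1))^2)`, a sharpness
#' proxy: the larger, the crisper the image. The forward differences exist
#' only on the `(M-1) x (N-1)` interior, which is the default averaging
#' domain; `denominator = "mn"` divides the same sum by `M * N` instead
#' (the two differ by O(1/M)).
#'
#' @param img `gray_image` or matrix with values in \[0, 1\].
#' @param scale Intensity scale factor applied before measuring
#'   (default 255).
#' @param denominator `"interior"` (default) or `"mn"`.
#' @return Nonnegative scalar.
#' @export
average_gradient <- function(img, scale = 255,
                             denominator = c("interior", "mn")) {
  denominator <- match.arg(denominator)
  f <- pixels(img) * scale
  M <- nrow(f); N <- ncol(f)
  if (M < 2L || N < 2L)
    stop("average gradient needs at least a 2 x 2 image", call. = FALSE)
  dr <- f[-M, -N] - f[-1, -N]   # f(i,j) - f(i+1,j)
  dc <- f[-M, -N] - f[-M, -1]   # f(i,j) - f(i,j+1)
  tot <- sum(sqrt(dr^2 + dc^2))
  tot / switch(denominator, interior = (M - 1) * (N - 1), mn = M * N)
}

#' Information entropy (H)
#'
#' Shannon entropy `-sum P(l) log2 P(l)` of the gray-level histogram over
#' `n_bins` equal-width bins, in bits (`0 * log 0 := 0`). Bounded above by
#' `log2(n_bins)`; a constant image scores 0.
#'
#' @param img `gray_image` or matrix with values in \[0, 1\].
#' @param n_bins Number of gray-level bins (default 256).
#' @return Entropy in bits.
#' @export
entropy <- function(img, n_bins = 256L) {
  px <- pixels(img)
  lev <- quantize_levels(clip01(px), as.integer(n_bins))
  p <- tabulate(lev + 1L, nbins = n_bins) / length(px)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Spatial frequency (SF)
#'
#' Quadrature combination `sqrt(RF^2 + CF^2)` of the row and column
#' activity, where `RF = sqrt(sum_(j>=2) (f(i,j) - f(i,j-1))^2 / (M*N))`
#' and `CF` is the transposed analogue — the root-mean-square first
#' difference with the full `M*N` pixel count in the denominator. An
#' overall activity proxy.
#'
#' @inheritParams average_gradient
#' @return Nonnegative scalar.
#' @export
spatial_frequency <- function(img, scale = 255) {
  f <- pixels(img) * scale
  M <- nrow(f); N <- ncol(f)
  if (M < 2L || N < 2L)
    stop("spatial frequency needs at least a 2 x 2 image", call. = FALSE)
  RF <- sqrt(sum((f[, -1] - f[, -N])^2) / (M * N))
  CF <- sqrt(sum((f[-1, ] - f[-M, ])^2) / (M * N))
  sqrt(RF^2 + CF^2)
}

# the 1/4-scaled 3x3 Sobel derivative templates (horizontal, vertical)
sobel_gx <- function() matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE) / 4
sobel_gy <- function() matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, byrow = TRUE) / 4

#' Edge intensity (EI)
#'
#' Mean Sobel gradient magnitude: the image is correlated with the
#' 1/4-scaled 3 x 3 Sobel templates and the per-pixel magnitude
#' `sqrt(Gx^2 + Gy^2)` is averaged. By default the average runs over the
#' `(M-2) x (N-2)` interior where the 3 x 3 support is fully valid (the
#' boundary-free convention, which makes analytic fixtures exact);
#' `border = "reflect"` instead pads by symmetric reflection and averages
#' over all pixels. Note the 1/4 scaling: a unit-slope ramp scores exactly
#' 2 (the template spans two pixels with unit weight per side).
#'
#' @inheritParams average_gradient
#' @param border `"interior"` (default) or `"reflect"`.
#' @return Nonnegative scalar.
#' @export
edge_intensity <- function(img, scale = 255, border = c("interior", "reflect")) {
  border <- match.arg(border)
  f <- pixels(img) * scale
  if (nrow(f) < 3L || ncol(f) < 3L)
    stop("edge intensity needs at least a 3 x 3 image", call. = FALSE)
  if (border == "reflect") f <- pad_reflect(f, 1L)
  Gx <- correlate3(f, sobel_gx())
  Gy <- correlate3(f, sobel_gy())
  mean(sqrt(Gx^2 + Gy^2))
}

# valid-region 3x3 correlation (kernel laid over the image unflipped)
correlate3 <- function(f, k) {
  M <- nrow(f); N <- ncol(f)
  out <- matrix(0, M - 2L, N - 2L)
  for (di in 0:2) for (dj in 0:2) {
    if (k[di + 1, dj + 1] == 0) next
    out <- out + k[di + 1, dj + 1] * f[(1 + di):(M - 2 + di), (1 + dj):(N - 2 + dj)]
  }
  out
}

#' Four-metric quality report for one image
#'
#' @param img `gray_image` or matrix.
#' @param image_id Identifier for the report row (defaults to the image's
#'   origin, or `"image"`).
#' @param scale Intensity scale for AG/SF/EI (default 255).
#' @param n_bins Histogram bins for the entropy (default 256).
#' @return One-row `data.frame` with columns `image_id`, `AG`, `H`, `SF`,
#'   `EI`.
#' @export
quality_report <- function(img, image_id = NULL, scale = 255, n_bins = 256L) {
  if (is.null(image_id))
    image_id <- if (inherits(img, "gray_image")) img$origin else "image"
  data.frame(image_id = image_id,
             AG = average_gradient(img, scale = scale),
             H = entropy(img, n_bins = n_bins),
             SF = spatial_frequency(img, scale = scale),
             EI = edge_intensity(img, scale = scale),
             stringsAsFactors = FALSE)
}

#' Batch quality report
#'
#' Scores every image in a directory (PNG/TIFF) or in a named list and
#' appends a `"mean"` row with the arithmetic column means — the form in
#' which enhancement results are usually averaged over an image set.
#'
#' @param x Directory path, or a (preferably named) list of images.
#' @param ... Passed to [quality_report()].
#' @return `data.frame` with one row per image plus a final mean row.
#' @export
batch_report <- function(x, ...) {
  imgs <- if (is.character(x) && length(x) == 1L) {
    paths <- list.files(x, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(paths) == 0L)
      stop("no PNG/TIFF images found in ", x, call. = FALSE)
    stats::setNames(lapply(paths, read_gray_image), basename(paths))
  } else if (is.list(x)) {
    if (length(x) == 0L) stop("empty image list", call. = FALSE)
    x
  } else stop("`x` must be a directory path or a list of images", call. = FALSE)
  ids <- names(imgs)
  if (is.null(ids)) ids <- sprintf("image_%02d", seq_along(imgs))
  rows <- mapply(function(im, id) quality_report(im, image_id = id, ...),
                 imgs, ids, SIMPLIFY = FALSE)
  tab <- do.call(rbind, rows)
  mean_row <- data.frame(image_id = "mean", AG = mean(tab$AG), H = mean(tab$H),
                         SF = mean(tab$SF), EI = mean(tab$EI),
                         stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  rbind(tab, mean_row)
}
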