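#' Plain gamma correction
#'
#' Applies the transform `T(v) = vmax * (v / vmax)^gamma` pointwise, with
#' `vmax` the maximum intensity present in the image. `gamma < 1` brightens
#' dark regions, `gamma > 1` darkens. An all-zero image is returned
#' unchanged (`vmax = 0` convention).
#'
#' @param img `gray_image` or nonnegative numeric matrix.
#' @param gamma Positive exponent.
#' @return Same type and shape.
#' @export
gamma_correct <- function(img, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("`gamma` must be a single positive number", call. = FALSE)
  px <- pixels(img)
  vmax <- max(px)
  if (vmax <= 0) return(img)
  with_pixels(img, vmax * (px / vmax)^gamma)
}

#' Weighted histogram distribution
#'
#' Compresses a probability histogram toward its mode:
#' `pdf_w(v) = pdf_max * ((pdf(v) - pdf_min) / (pdf_max - pdf_min))^alpha`.
#' Small `alpha` flattens the weighting (all occupied levels pulled toward
#' `pdf_max`), large `alpha` concentrates it on the modal level; the argmax
#' is preserved for every `alpha`. A constant pdf (`pdf_max == pdf_min`) is
#' returned unchanged (documented degenerate convention).
#'
#' @param pdf Nonnegative probability vector (need not sum to 1).
#' @param alpha Positive adjustment parameter.
#' @return Numeric vector of the same length, entries in `[0, pdf_max]`.
#' @export
weighted_distribution <- function(pdf, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("`alpha` must be a single positive number", call. = FALSE)
  if (any(pdf < 0)) stop("`pdf` entries must be nonnegative", call. = FALSE)
  pmax_ <- max(pdf); pmin_ <- min(pdf)
  if (pmax_ == pmin_) return(pdf)
  pmax_ * ((pdf - pmin_) / (pmax_ - pmin_))^alpha
}

#' Adaptive gamma correction with weighting distribution
#'
#' Contrast correction driven by the image's own histogram. The intensity
#' range `[0, vmax]` is quantized into `n_levels` gray levels; the level
#' histogram `pdf` is compressed with [weighted_distribution()]; its
#' normalized running sum `cdf_w` yields a per-level exponent
#' `gamma(v) = 1 - cdf_w(v)`, looked up per quantized level and applied to
#' the pixel's own value: `T(v) = vmax * (v / vmax)^gamma(v)`. Because
#' X-ray intensities
#' mass densely in the low grayscale range, `cdf_w` rises early, the
#' exponent drops below 1 for most levels, and dark pixels are raised
#' without the over-enhancement of a single global gamma.
#'
#' Endpoints are preserved exactly: `T(vmax) = vmax`, and `T(0) = 0` by the
#' convention `0^0 := 0` for this map (relevant only for degenerate
#' histograms whose weighted mass sits entirely at level 0). The per-level
#' map is monotone non-decreasing, and on nonnegative input `T(v) >= v`
#' pointwise when intensities lie in \[0, 1\] (the exponent never exceeds 1).
#'
#' @param img `gray_image` or nonnegative numeric matrix.
#' @param alpha Positive weighting parameter (default 0.5, a moderate
#'   histogram compression).
#' @param n_levels Number of quantized gray levels for the histogram
#'   (default 256).
#' @return Same type and shape, intensities in `[0, vmax]`.
#' @export
agcwd_enhance <- function(img, alpha = 0.5, n_levels = 256L) {
  px <- pixels(img)
  if (any(px < 0)) stop("AGCWD expects nonnegative intensities", call. = FALSE)
  vmax <- max(px)
  if (vmax <= 0 || min(px) == vmax) return(img)  # constant image: identity
  n_levels <- as.integer(n_levels)
  u <- px / vmax
  lev <- quantize_levels(u, n_levels)
  gam <- agcwd_gamma(lev, n_levels, alpha)
  out <- u^gam[lev + 1L]
  out[u == 0] <- 0   # 0^0 := 0 so the black point stays fixed
  with_pixels(img, matrix(vmax * out, nrow(px), ncol(px)))
}

# Per-level adaptive exponent gamma(v) = 1 - cdf_w(v) from the weighted
# histogram of the quantized levels (0-based), over n gray levels.
agcwd_gamma <- function(lev, n, alpha) {
  pdf <- tabulate(lev + 1L, nbins = n) / length(lev)
  pdf_w <- weighted_distribution(pdf, alpha)
  tot <- sum(pdf_w)
  cdf_w <- if (tot > 0) cumsum(pdf_w) / tot else cumsum(pdf)
  1 - cdf_w
}
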