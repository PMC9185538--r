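#' Nonsubsampled shearlet transform configuration
#'
#' The transform is parameterized by the number of scale levels `levels`
#' (written j in the shearlet literature) and one shearing parameter
#' `l_k` per level; level k is split into `2^l_k` directional sub-bands.
#' The package default, `levels = 4` with shearing parameters
#' `(2, 2, 2, 2)` (4 directions per level), is the configuration the
#' parameter sweeps identify as the best cost/quality trade-off.
#'
#' @param levels Number of scale decomposition levels, 1..6.
#' @param shear Integer vector of length `levels`, each entry in 1..5;
#'   level k yields `2^shear[k]` directional bands.
#' @return An object of class `nsst_config`.
#' @export
#' @examples
#' nsst_config()                    # 4 levels, 4 directions each
#' nsst_config(3, c(2, 3, 4))      # direction counts 4, 8, 16
nsst_config <- function(levels = 4L, shear = rep(2L, levels)) {
  levels <- as.integer(levels)
  shear <- as.integer(shear)
  if (length(levels) != 1L || levels < 1L || levels > 6L)
    stop("`levels` must be a single integer in 1..6", call. = FALSE)
  if (length(shear) != levels)
    stop("`shear` must have one entry per level (length ", levels, ")", call. = FALSE)
  if (any(shear < 1L) || any(shear > 5L))
    stop("shearing parameters must lie in 1..5", call. = FALSE)
  structure(list(levels = levels, shear = shear), class = "nsst_config")
}

#' @export
print.nsst_config <- function(x, ...) {
  cat(sprintf("<nsst_config> %d levels, directions (%s)\n",
              x$levels, paste(2^x$shear, collapse = ", ")))
  invisible(x)
}

#' Build the directional shearing filter bank for one level
#'
#' Constructs `2^l` real, nonnegative frequency-domain windows on a
#' pseudo-polar partition of the frequency plane. Each frequency sample is
#' assigned a shear coordinate: slope `v/u` on the horizontal cone
#' (`|u| >= |v|`) and `2 - u/v` on the vertical cone, giving a continuous
#' periodic coordinate of period 4 over the projective line of directions.
#' Smooth raised-cosine (Meyer-type) bumps centered on `2^l` equispaced
#' directions are laid on this coordinate and then normalized pointwise so
#' the windows sum to exactly 1 at every frequency sample — the partition
#' of unity that makes the system a tight frame and the inverse transform a
#' plain sum. Because the shear coordinate is invariant under
#' `(u, v) -> (-u, -v)`, every window has the conjugate symmetry of a real
#' impulse response.
#'
#' @param shape Integer vector `(M, N)`, both at least 8.
#' @param l Shearing parameter, 1..5; produces `2^l` windows.
#' @return List of `2^l` numeric `M x N` matrices summing pointwise to 1.
#' @export
build_shear_filters <- function(shape, l) {
  M <- as.integer(shape[1]); N <- as.integer(shape[2])
  l <- as.integer(l)
  if (M < 8L || N < 8L)
    stop("image too small for directional decomposition (need at least 8 x 8)",
         call. = FALSE)
  if (l < 1L || l > 5L) stop("shearing parameter must lie in 1..5", call. = FALSE)
  nd <- 2L^l
  if (nd > min(M, N))
    stop("image too small for ", nd, " shearing directions", call. = FALSE)
  u <- matrix(dft_freq(M), M, N)        # row frequency
  v <- matrix(dft_freq(N), M, N, byrow = TRUE)  # column frequency
  horiz <- abs(u) >= abs(v)
  P <- matrix(0, M, N)
  P[horiz] <- v[horiz] / u[horiz]       # slope in [-1, 1]
  P[!horiz] <- 2 - u[!horiz] / v[!horiz]  # continues through the vertical cone
  dc <- u == 0 & v == 0
  h <- 4 / nd                            # center spacing on the period-4 coordinate
  centers <- -1 + (seq_len(nd) - 0.5) * h
  W <- vector("list", nd)
  # a DFT sample at the Nyquist row/column stands for +n/2 and -n/2 at once;
  # averaging each window with its point reflection makes w(u,v) = w(-u,-v)
  # hold exactly there too (real impulse responses), and preserves the
  # pointwise sum
  neg <- function(w) w[c(1, M:2), c(1, N:2)]
  for (d in seq_len(nd)) {
    dist <- abs((P - centers[d] + 2) %% 4 - 2)   # circular distance, period 4
    w <- cos(pi / 2 * pmin(dist / h, 1))^2       # smooth bump, half-width h
    w[dc] <- 1 / nd                              # direction undefined at DC
    W[[d]] <- (w + neg(w)) / 2
  }
  S <- Reduce(`+`, W)
  lapply(W, function(w) w / S)
}

#' Undecimated two-channel pyramid decomposition
#'
#' Splits an image into a coarse approximation plus `j` bandpass bands with
#' an a-trous (undecimated) pyramid: at level k the running approximation is
#' low-pass filtered with the separable maxflat kernel
#' `[1, 4, 6, 4, 1]/16` upsampled by `2^k` (zeros inserted between taps),
#' and the bandpass band is the difference between successive
#' approximations. The decomposition is additive by construction —
#' `low + sum(bandpass)` reproduces the input to floating-point precision —
#' and every band keeps the source shape (no downsampling). Filtering is
#' circular, so the pyramid is exactly linear and shift covariant.
#'
#' @param img Numeric matrix or `gray_image`.
#' @param j Number of bandpass levels, at least 1.
#' @return List with elements `low` (matrix) and `bandpass` (list of `j`
#'   matrices, finest scale first).
#' @export
pyramid_decompose <- function(img, j) {
  x <- pixels(img)
  if (!all(is.finite(x))) stop("non-finite values in input image", call. = FALSE)
  j <- as.integer(j)
  if (j < 1L) stop("`j` must be at least 1", call. = FALSE)
  M <- nrow(x); N <- ncol(x)
  A <- fft2(x)
  bands <- vector("list", j)
  for (k in seq_len(j)) {
    H <- atrous_lowpass_freq(M, N, k - 1L)
    A_next <- A * H
    bands[[k]] <- Re(ifft2(A - A_next))
    A <- A_next
  }
  list(low = Re(ifft2(A)), bandpass = bands)
}

# Frequency response of the separable pyramid low-pass upsampled by
# 2^level. The 9-tap CDF 9/7 analysis low-pass (renormalized to unit DC
# gain) gives a sharper scale separation than the short maxflat kernel, so
# successive pyramid levels carve out clean octaves.
atrous_lowpass_freq <- function(M, N, level) {
  h <- c(0.026748757411, -0.016864118443, -0.078223266529, 0.266864118443,
         0.602949018236, 0.266864118443, -0.078223266529, -0.016864118443,
         0.026748757411)
  h <- h / sum(h)
  r <- 4L
  step <- 2L^level
  off <- expand.grid(dr = (-r:r) * step, dc = (-r:r) * step)
  w <- (h %o% h)[cbind(off$dr / step + r + 1L, off$dc / step + r + 1L)]
  kernel_freq(M, N, as.matrix(off), w)
}

#' Forward nonsubsampled shearlet transform
#'
#' Decomposes the image with [pyramid_decompose()] and splits each bandpass
#' band into its level's directional sub-bands by frequency-domain
#' multiplication with the [build_shear_filters()] windows. Since the
#' windows form a pointwise partition of unity, the directional bands of a
#' level sum back to that level's bandpass band exactly.
#'
#' @param img `gray_image` or numeric matrix.
#' @param config An [nsst_config()].
#' @return An object of class `nsst_bands`: list with `low` (matrix),
#'   `high` (list of `levels` lists of directional band matrices, finest
#'   scale first), `config`, and `shape`.
#' @export
nsst_forward <- function(img, config = nsst_config()) {
  x <- pixels(img)
  stopifnot(inherits(config, "nsst_config"))
  M <- nrow(x); N <- ncol(x)
  pyr <- pyramid_decompose(x, config$levels)
  banks <- filter_bank_cache(c(M, N), config$shear)
  high <- vector("list", config$levels)
  for (k in seq_len(config$levels)) {
    Bhat <- fft2(pyr$bandpass[[k]])
    high[[k]] <- lapply(banks[[as.character(config$shear[k])]],
                        function(W) Re(ifft2(Bhat * W)))
  }
  structure(list(low = pyr$low, high = high, config = config, shape = c(M, N)),
            class = "nsst_bands")
}

# build each distinct per-level filter bank once
filter_bank_cache <- function(shape, shear) {
  banks <- list()
  for (l in unique(shear)) banks[[as.character(l)]] <- build_shear_filters(shape, l)
  banks
}

#' Inverse nonsubsampled shearlet transform
#'
#' Recombines a set of sub-bands into an image: the directional bands of
#' each level are summed into a bandpass band (exact, by the partition of
#' unity of the analysis windows) and the additive pyramid is collapsed as
#' `low + sum(bandpass)`. `nsst_inverse(nsst_forward(x))` reproduces `x` to
#' floating-point precision (perfect reconstruction of the tight frame).
#'
#' @param bands An `nsst_bands` object (sub-bands may have been modified).
#' @return `gray_image` with the reconstructed intensities (not clipped).
#' @export
nsst_inverse <- function(bands) {
  stopifnot(inherits(bands, "nsst_bands"))
  shp <- bands$shape
  check_band_shape(bands$low, shp)
  out <- bands$low
  for (k in seq_along(bands$high)) {
    lev <- bands$high[[k]]
    if (length(lev) != 2^bands$config$shear[k])
      stop("level ", k, " has ", length(lev), " directional bands, expected ",
           2^bands$config$shear[k], call. = FALSE)
    for (b in lev) {
      check_band_shape(b, shp)
      out <- out + b
    }
  }
  # deliberately unclipped: callers that modified sub-bands decide how to
  # map the reconstruction back into display range
  gray_image(out, origin = "nsst_inverse", normalize = FALSE)
}

check_band_shape <- function(b, shp) {
  if (!is.matrix(b) || nrow(b) != shp[1] || ncol(b) != shp[2])
    stop("sub-band shape mismatch: expected ", shp[1], " x ", shp[2], call. = FALSE)
  invisible(TRUE)
}

#' @export
print.nsst_bands <- function(x, ...) {
  cat(sprintf("<nsst_bands> %d x %d, %d levels, directions (%s)\n",
              x$shape[1], x$shape[2], x$config$levels,
              paste(2^x$config$shear, collapse = ", ")))
  invisible(x)
}

#' Serialize a sub-band set to a directory
#'
#' Writes each sub-band as a 16-bit TIFF (linearly stretched to \[0, 1\] for
#' storage) plus a JSON manifest recording levels, shearing parameters,
#' shape and per-band value ranges, for inspection and debugging. The
#' enhancement pipeline itself never round-trips through this
#' representation.
#'
#' @param bands An `nsst_bands` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_subbands <- function(bands, dir) {
  stopifnot(inherits(bands, "nsst_bands"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ranges <- list(low = range(bands$low))
  write_gray_image(linear_stretch(bands$low), file.path(dir, "low.tif"), bits = 16L)
  for (k in seq_along(bands$high)) {
    for (d in seq_along(bands$high[[k]])) {
      nm <- sprintf("high_L%d_D%02d", k, d)
      ranges[[nm]] <- range(bands$high[[k]][[d]])
      write_gray_image(linear_stretch(bands$high[[k]][[d]]),
                       file.path(dir, paste0(nm, ".tif")), bits = 16L)
    }
  }
  manifest <- list(levels = bands$config$levels, shear = bands$config$shear,
                   shape = bands$shape, ranges = ranges)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
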