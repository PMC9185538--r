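#' Gradient-domain guided filter parameters
#'
#' @param radius Window radius (the filter window is the
#'   `(2*radius+1) x (2*radius+1)` square); default 16.
#' @param lam Regularization strength on the local slope; default 0.5 on
#'   the normalized \[0, 1\] intensity scale.
#' @param xi Detail gain of the boosting step (`>= 0`); default 5. `xi = 1`
#'   makes the whole enhance step the identity, `xi = 0` returns the
#'   smoothed band.
#' @param eps Variance floor of the edge-aware weight, `(0.001 * L)^2` with
#'   the normalized dynamic range `L = 1`, i.e. `1e-6`.
#' @param weight_mode How the edge-aware weight enters the regularizer:
#'   `"divide"` (default) uses an effective `lam / Gamma` — weaker
#'   smoothing where the weight flags an edge — while `"multiply"` uses
#'   `lam * Gamma`.
#' @return An object of class `gdgf_params`.
#' @export
gdgf_params <- function(radius = 16L, lam = 0.5, xi = 5, eps = 1e-6,
                        weight_mode = c("divide", "multiply")) {
  radius <- as.integer(radius)
  if (radius < 1L) stop("`radius` must be a positive integer", call. = FALSE)
  if (lam <= 0) stop("`lam` must be positive", call. = FALSE)
  if (xi < 0) stop("`xi` must be nonnegative", call. = FALSE)
  if (eps < 0) stop("`eps` must be nonnegative", call. = FALSE)
  structure(list(radius = radius, lam = lam, xi = xi, eps = eps,
                 weight_mode = match.arg(weight_mode)),
            class = "gdgf_params")
}

#' @export
print.gdgf_params <- function(x, ...) {
  cat(sprintf("<gdgf_params> radius %d, lam %g, xi %g, eps %g, weight_mode %s\n",
              x$radius, x$lam, x$xi, x$eps, x$weight_mode))
  invisible(x)
}

#' Sliding-window mean (box filter)
#'
#' Per-pixel mean over the `(2*radius+1)^2` square window, with symmetric
#' boundary reflection (edge row/column included in the mirror). Computed
#' as two separable 1-D moving sums, each from a cumulative sum along a
#' single axis — deliberately not a 2-D integral image, whose full-image
#' cumulative sums cancel catastrophically when window variances of
#' near-constant regions are formed downstream.
#'
#' @param x Numeric matrix.
#' @param radius Window radius; must be less than both image dimensions.
#' @return Matrix of window means, same shape as `x`.
#' @export
box_mean <- function(x, radius) {
  r <- as.integer(radius)
  M <- nrow(x); N <- ncol(x)
  if (r < 1L || r >= M || r >= N)
    stop("`radius` must be in 1..(min(dim) - 1)", call. = FALSE)
  w <- 2L * r + 1L
  P <- moving_sum_rows(pad_reflect(x, r), w)        # collapse row axis
  out <- t(moving_sum_rows(t(P), w))                # then column axis
  out / w^2
}

# centered moving sum of length w down each column; drops the (w-1)/2
# invalid entries at each end
moving_sum_rows <- function(P, w) {
  S <- rbind(0, apply(P, 2, cumsum))
  n <- nrow(P)
  S[(w + 1):(n + 1), , drop = FALSE] - S[1:(n + 1 - w), , drop = FALSE]
}

# symmetric (mirror, edge included) padding by r on all sides
pad_reflect <- function(x, r) {
  ri <- c(r:1, seq_len(nrow(x)), nrow(x):(nrow(x) - r + 1))
  ci <- c(r:1, seq_len(ncol(x)), ncol(x):(ncol(x) - r + 1))
  x[ri, ci, drop = FALSE]
}

# Per-pixel population standard deviation over the (2r+1)^2 window.
# Variances within 1e-12 of the image's largest window variance are pure
# moment-cancellation residue (the two box means agree to machine
# precision); they are zeroed so exactly flat regions report exactly zero
# deviation instead of a ~1e-8 rounding floor, which would otherwise be
# amplified by the (chi + eps) ratios downstream.
local_sd <- function(x, r) {
  v <- box_mean(x * x, r) - box_mean(x, r)^2
  vmax <- max(v)
  if (vmax > 0) v[v < 1e-12 * vmax] <- 0
  sqrt(pmax(v, 0))
}

#' Edge-aware weight field
#'
#' Computes the three per-pixel quantities steering the gradient-domain
#' guided filter:
#' * `chi`, the product of the local standard deviations at radius 1
#'   (3 x 3 window) and at the filter radius — large only where fine and
#'   coarse variation coincide, i.e. at genuine edges;
#' * `Gamma`, the edge-aware weight
#'   `(1/N) * sum_p (chi(p') + eps) / (chi(p) + eps)` over all `N` pixels —
#'   above 1 at edges, below 1 in smooth regions;
#' * `gamma_factor`, the logistic edge factor
#'   `1 - 1 / (1 + exp(eta * (chi - mean(chi))))` with
#'   `eta = 4 / (mean(chi) - min(chi))` — close to 1 on edges, close to 0
#'   in flat regions, used to pull the local regression slope toward 1 at
#'   edges.
#'
#' For a constant guide (`chi` identically 0) the smooth-region limit is
#' taken: `Gamma` is 1 everywhere and `gamma_factor` 0 everywhere.
#'
#' @param G Guide image matrix.
#' @param radius Filter window radius.
#' @param eps Variance floor (default `1e-6`, i.e. `(0.001 * L)^2` on the
#'   normalized scale).
#' @return List with matrices `chi`, `Gamma`, `gamma_factor` and the scalar
#'   `eta` (`NA` in the degenerate case).
#' @export
edge_weight <- function(G, radius, eps = 1e-6) {
  if (!all(is.finite(G))) stop("non-finite values in guide image", call. = FALSE)
  chi <- local_sd(G, 1L) * local_sd(G, as.integer(radius))
  Gamma <- (chi + eps) * mean(1 / (chi + eps))
  mu <- mean(chi); mn <- min(chi)
  if (mu - mn <= 0) {
    gf <- matrix(0, nrow(G), ncol(G))   # smooth-region limit
    eta <- NA_real_
  } else {
    eta <- 4 / (mu - mn)
    gf <- 1 - 1 / (1 + exp(eta * (chi - mu)))
  }
  list(chi = chi, Gamma = Gamma, gamma_factor = gf, eta = eta)
}

#' Gradient-domain guided filter
#'
#' Edge-preserving smoothing of `X` steered by a guide `G` through the
#' local linear model `Z = a * G + b` fit per window: the slope
#' `a = (cov_w(G, X) + lam_eff * gamma_factor) / (var_w(G) + lam_eff)` with
#' window statistics at the filter radius, `lam_eff` the regularization
#' modulated by the edge-aware weight (see [gdgf_params()] `weight_mode`),
#' and `b = mean_w(X) - a * mean_w(G)`; the output averages the
#' per-window coefficients over all windows covering each pixel. At edges
#' `gamma_factor` pushes the slope toward 1 (the filter transmits the
#' edge); in flat regions the slope shrinks toward 0 and the window mean
#' dominates (the filter smooths).
#'
#' @param X Matrix to filter.
#' @param G Guide matrix, same shape as `X` (use `G = X` for self-guided
#'   denoising).
#' @param params A [gdgf_params()].
#' @return Filtered matrix, same shape.
#' @export
gdgf_filter <- function(X, G, params = gdgf_params()) {
  if (!is.matrix(X) || !is.matrix(G) || !all(dim(X) == dim(G)))
    stop("`X` and `G` must be matrices of the same shape", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(G)))
    stop("non-finite values in input", call. = FALSE)
  r <- params$radius
  ew <- edge_weight(G, r, params$eps)
  lam_eff <- switch(params$weight_mode,
                    divide = params$lam / ew$Gamma,
                    multiply = params$lam * ew$Gamma)
  muG <- box_mean(G, r)
  muX <- box_mean(X, r)
  covGX <- box_mean(G * X, r) - muG * muX
  varG <- box_mean(G * G, r) - muG^2
  a <- (covGX + lam_eff * ew$gamma_factor) / (varG + lam_eff)
  b <- muX - a * muG
  box_mean(a, r) * G + box_mean(b, r)
}

#' Detail boosting
#'
#' Adds back `xi` times the residual between the original and the smoothed
#' band: `Z + xi * (X - Z)`. `xi = 1` returns `X` exactly (the algebraic
#' collapse is short-circuited so no floating-point residue is introduced),
#' `xi = 0` returns `Z`; the map is affine in `xi`.
#'
#' @param X Original band matrix.
#' @param Z Smoothed band matrix, same shape.
#' @param xi Detail gain.
#' @return Matrix `Z + xi * (X - Z)`.
#' @export
detail_boost <- function(X, Z, xi) {
  if (!all(dim(X) == dim(Z)))
    stop("`X` and `Z` must have the same shape", call. = FALSE)
  if (xi == 1) return(X)
  Z + xi * (X - Z)
}

#' Denoise and sharpen one detail sub-band
#'
#' Self-guided gradient-domain filtering (`G = X`, the sub-band itself)
#' followed by [detail_boost()]: noise in flat regions is averaged away by
#' the filter, then the residual detail is amplified by `xi`. Sub-bands are
#' signed and processed as such; no offset is applied.
#'
#' @param band Detail sub-band matrix.
#' @param params A [gdgf_params()].
#' @return Enhanced band, same shape.
#' @export
enhance_subband <- function(band, params = gdgf_params()) {
  Z <- gdgf_filter(band, band, params)
  detail_boost(band, Z, params$xi)
}
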