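# Frequency-domain helpers. All filtering in the transform is circular
# (periodic boundary), which makes linearity and shift covariance exact.
# DFT sample layout: entry (i, j) of an M x N spectrum corresponds to the
# frequency pair (fr(i), fc(j)) with fr(i) = i - 1 for i - 1 <= M/2 and
# i - 1 - M otherwise (zero frequency at the grid origin (1, 1)).

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# signed DFT frequency indices for n samples
dft_freq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n / 2, k, k - n)
}

# Frequency response (complex matrix) of a small kernel placed on the M x N
# grid with circular wrap. `offsets` is a 2-column matrix of (row, col)
# displacements relative to the kernel center, `weights` the tap values.
kernel_freq <- function(M, N, offsets, weights) {
  k <- matrix(0, M, N)
  i <- (offsets[, 1] %% M) + 1L
  j <- (offsets[, 2] %% N) + 1L
  for (t in seq_along(weights)) k[i[t], j[t]] <- k[i[t], j[t]] + weights[t]
  fft2(k)
}

# circular convolution of an image with a precomputed frequency response
freq_filter <- function(x, H) Re(ifft2(fft2(x) * H))

# Circular Gaussian blur via the frequency domain (used by the phantom
# generator; sigma in pixels, truncated at 4 sigma).
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  M <- nrow(x); N <- ncol(x)
  r <- min(ceiling(4 * sigma), floor((min(M, N) - 1) / 2))
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g <- g / sum(g)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  w <- g[off$dr + r + 1] * g[off$dc + r + 1]
  H <- kernel_freq(M, N, as.matrix(off), w)
  freq_filter(x, H)
}
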