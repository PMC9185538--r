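# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (double loops, hand-rolled statistics) so they share no
# code path with the implementation they check.

rand_img <- function(M, N, seed) {
  set.seed(seed)
  matrix(runif(M * N), M, N)
}

# cached standard fixture suite (chest/texture phantoms are 440x440)
suite_fixtures <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- standard_suite()
    cache
  }
})

# ---- window-statistics oracles (symmetric reflection boundary) ----------

# naive window extraction: reflect-padded values in the (2r+1)^2 window at (i, j)
window_vals <- function(x, i, j, r) {
  M <- nrow(x); N <- ncol(x)
  refl <- function(k, n) {
    # symmetric reflection with the edge sample included
    while (k < 1 || k > n) {
      if (k < 1) k <- 1 - k
      if (k > n) k <- 2 * n + 1 - k
    }
    k
  }
  v <- numeric((2 * r + 1)^2)
  t <- 0
  for (di in -r:r) for (dj in -r:r) {
    t <- t + 1
    v[t] <- x[refl(i + di, M), refl(j + dj, N)]
  }
  v
}

naive_box_mean <- function(x, r) {
  out <- x
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x)))
    out[i, j] <- mean(window_vals(x, i, j, r))
  out
}

naive_sd <- function(x, r) {
  out <- x
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    v <- window_vals(x, i, j, r)
    out[i, j] <- sqrt(max(mean(v^2) - mean(v)^2, 0))
  }
  out
}

# direct per-pixel evaluation of the edge-aware weight definitions
naive_edge_weight <- function(G, r, eps = 1e-6) {
  chi <- naive_sd(G, 1) * naive_sd(G, r)
  N <- length(G)
  Gamma <- chi
  for (i in seq_len(nrow(G))) for (j in seq_len(ncol(G)))
    Gamma[i, j] <- sum((chi[i, j] + eps) / (chi + eps)) / N
  mu <- mean(chi); mn <- min(chi)
  if (mu - mn <= 0) {
    gf <- matrix(0, nrow(G), ncol(G))
  } else {
    eta <- 4 / (mu - mn)
    gf <- 1 - 1 / (1 + exp(eta * (chi - mu)))
  }
  list(chi = chi, Gamma = Gamma, gamma_factor = gf)
}

# window-by-window evaluation of the guided-filter regression + recombination
naive_gdgf <- function(X, G, r, lam, eps = 1e-6, weight_mode = "divide") {
  ew <- naive_edge_weight(G, r, eps)
  M <- nrow(X); N <- ncol(X)
  a <- b <- X
  for (i in seq_len(M)) for (j in seq_len(N)) {
    g <- window_vals(G, i, j, r)
    x <- window_vals(X, i, j, r)
    lam_eff <- if (weight_mode == "divide") lam / ew$Gamma[i, j] else lam * ew$Gamma[i, j]
    num <- mean(g * x) - mean(g) * mean(x) + lam_eff * ew$gamma_factor[i, j]
    den <- (mean(g^2) - mean(g)^2) + lam_eff
    a[i, j] <- num / den
    b[i, j] <- mean(x) - a[i, j] * mean(g)
  }
  naive_box_mean(a, r) * G + naive_box_mean(b, r)
}

# ---- metric oracles ------------------------------------------------------

naive_ag <- function(f) {
  M <- nrow(f); N <- ncol(f)
  tot <- 0
  for (i in 1:(M - 1)) for (j in 1:(N - 1))
    tot <- tot + sqrt((f[i, j] - f[i + 1, j])^2 + (f[i, j] - f[i, j + 1])^2)
  tot / ((M - 1) * (N - 1))
}

naive_sf <- function(f) {
  M <- nrow(f); N <- ncol(f)
  rf <- cf <- 0
  for (i in 1:M) for (j in 2:N) rf <- rf + (f[i, j] - f[i, j - 1])^2
  for (j in 1:N) for (i in 2:M) cf <- cf + (f[i, j] - f[i - 1, j])^2
  sqrt(rf / (M * N) + cf / (M * N))
}

naive_ei <- function(f) {
  gx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE) / 4
  gy <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, byrow = TRUE) / 4
  M <- nrow(f); N <- ncol(f)
  tot <- 0
  for (i in 2:(M - 1)) for (j in 2:(N - 1)) {
    Gx <- Gy <- 0
    for (di in -1:1) for (dj in -1:1) {
      Gx <- Gx + f[i + di, j + dj] * gx[di + 2, dj + 2]
      Gy <- Gy + f[i + di, j + dj] * gy[di + 2, dj + 2]
    }
    tot <- tot + sqrt(Gx^2 + Gy^2)
  }
  tot / ((M - 2) * (N - 2))
}

naive_entropy <- function(f, n_bins = 256) {
  lev <- pmin(floor(f * n_bins), n_bins - 1)
  p <- tabulate(lev + 1, nbins = n_bins) / length(f)
  p <- p[p > 0]
  -sum(p * log2(p))
}
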