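test_that("box_mean equals the naive window average under reflection padding", {
  expect_equal(box_mean(matrix(0.3, 6, 6), 2), matrix(0.3, 6, 6))  # constant
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  bm <- box_mean(imp, 1)
  expect_equal(bm[4:6, 4:6], matrix(1 / 9, 3, 3))   # 3x3 normalization
  expect_equal(bm[1:2, 1:2], matrix(0, 2, 2))
  x <- rand_img(16, 16, 7)
  for (r in c(1, 3, 5)) expect_equal(box_mean(x, r), naive_box_mean(x, r),
                                     tolerance = 1e-12)
  # non-square images and the boundary reflection specifically
  y <- rand_img(7, 12, 8)
  expect_equal(box_mean(y, 2), naive_box_mean(y, 2), tolerance = 1e-12)
  expect_error(box_mean(y, 7), "radius")
})

test_that("edge weight fields match per-pixel evaluation of their definitions", {
  # constant guide: chi = 0, Gamma = 1, gamma_factor = 0 (smooth limit)
  ew <- edge_weight(matrix(0.5, 8, 8), 2)
  expect_equal(ew$chi, matrix(0, 8, 8))
  expect_equal(ew$Gamma, matrix(1, 8, 8))
  expect_equal(ew$gamma_factor, matrix(0, 8, 8))
  expect_true(is.na(ew$eta))
  # 8x8 two-region step image against the double-loop oracle
  step <- matrix(0.1, 8, 8); step[, 5:8] <- 0.9
  ew <- edge_weight(step, 2)
  or <- naive_edge_weight(step, 2)
  expect_equal(ew$chi, or$chi, tolerance = 1e-12)
  expect_equal(ew$Gamma, or$Gamma, tolerance = 1e-12)
  # the logistic's steep slope (eta ~ 1/chi-spread) amplifies the ~1e-13
  # arithmetic difference between running-sum and naive window statistics
  expect_equal(ew$gamma_factor, or$gamma_factor, tolerance = 1e-6)
  # the weight's ratio structure: mean is 1 for constant chi and >= 1 always
  # (arithmetic-vs-harmonic mean), and the factor stays inside [0, 1]
  expect_gte(mean(ew$Gamma), 1)
  expect_true(all(ew$gamma_factor >= 0 & ew$gamma_factor <= 1))
})

test_that("edge factor separates step edges from flat regions", {
  step <- matrix(0.1, 24, 24); step[, 13:24] <- 0.9
  step <- step + rand_img(24, 24, 99) * 0.01
  ew <- edge_weight(step, 4)
  expect_gt(mean(ew$gamma_factor[, 12:13]), 0.9)   # on the edge
  expect_lt(mean(ew$gamma_factor[, c(1:6, 19:24)]), 0.1)  # far from it
})

test_that("gdgf_filter matches the brute-force window-regression oracle", {
  for (cs in list(list(n = 16, r = 1), list(n = 16, r = 2), list(n = 16, r = 4))) {
    X <- rand_img(cs$n, cs$n, 50 + cs$r)
    Z <- gdgf_filter(X, X, gdgf_params(radius = cs$r, lam = 0.5))
    expect_equal(Z, naive_gdgf(X, X, cs$r, 0.5), tolerance = 1e-10)
  }
  # cross-guide case and the printed multiply convention
  X <- rand_img(12, 12, 61); G <- rand_img(12, 12, 62)
  pm <- gdgf_params(radius = 2, lam = 0.3, weight_mode = "multiply")
  expect_equal(gdgf_filter(X, G, pm),
               naive_gdgf(X, G, 2, 0.3, weight_mode = "multiply"), tolerance = 1e-10)
  expect_error(gdgf_filter(X, matrix(0, 3, 3), gdgf_params()), "same shape")
})

test_that("identity and degenerate limits of the filter hold", {
  X <- rand_img(16, 16, 71)
  # G = X with vanishing regularization: exact self-regression, Z -> X
  Z <- gdgf_filter(X, X, gdgf_params(radius = 2, lam = 1e-12))
  expect_lt(max(abs(Z - X)), 1e-6)
  # constant X with constant G is recovered exactly
  C <- matrix(0.4, 16, 16)
  expect_lt(max(abs(gdgf_filter(C, C, gdgf_params(radius = 3)) - 0.4)), 1e-12)
})

test_that("detail boost is exactly affine in its gain", {
  X <- rand_img(8, 8, 81); Z <- rand_img(8, 8, 82)
  expect_identical(detail_boost(X, Z, 1), Z + (X - Z))
  expect_equal(detail_boost(X, Z, 1), X, tolerance = 1e-15)
  expect_equal(detail_boost(X, Z, 0), Z)
  d <- X - Z
  expect_equal(detail_boost(X, Z, 5), Z + 5 * d, tolerance = 1e-12)
  # affine combination: boost at (xi1+xi2)/2 is the mean of the two boosts
  b1 <- detail_boost(X, Z, 2); b3 <- detail_boost(X, Z, 4)
  expect_equal(detail_boost(X, Z, 3), (b1 + b3) / 2, tolerance = 1e-12)
})

test_that("sub-band enhancement denoises flat regions and keeps the step", {
  # xi = 1 short-circuits to the identity regardless of the other knobs
  band <- rand_img(20, 20, 91) - 0.5
  expect_equal(enhance_subband(band, gdgf_params(radius = 3, lam = 2, xi = 1)),
               band, tolerance = 1e-15)
  expect_equal(enhance_subband(matrix(0, 16, 16), gdgf_params(radius = 2)),
               matrix(0, 16, 16))
  # noisy step: flat-region variance must fall at xi = 0 (pure smoothing),
  # while the step amplitude survives within 10%
  step <- matrix(-0.25, 32, 32); step[, 17:32] <- 0.25
  noisy <- step + rand_img(32, 32, 92) * 0.05 - 0.025
  sm <- enhance_subband(noisy, gdgf_params(radius = 4, lam = 0.1, xi = 0))
  flat <- cbind(sm[, 3:12], sm[, 21:30])
  flat_in <- cbind(noisy[, 3:12], noisy[, 21:30])
  expect_lt(stats::var(as.vector(flat)), stats::var(as.vector(flat_in)))
  amp_in <- mean(noisy[, 17:32]) - mean(noisy[, 1:16])
  amp_out <- mean(sm[, 17:32]) - mean(sm[, 1:16])
  expect_lt(abs(amp_out - amp_in) / amp_in, 0.1)
})

test_that("gradient-domain weighting preserves edges better than its ablation", {
  # same filter with gamma_factor forced off = plain weighted guided filter
  plain_wgif <- function(X, r, lam, eps = 1e-6) {
    ew <- edge_weight(X, r, eps)
    lam_eff <- lam / ew$Gamma
    muG <- box_mean(X, r); varG <- box_mean(X * X, r) - muG^2
    a <- varG / (varG + lam_eff)
    b <- muG - a * muG
    box_mean(a, r) * X + box_mean(b, r)
  }
  step <- matrix(-0.25, 32, 32); step[, 17:32] <- 0.25
  noisy <- step + rand_img(32, 32, 93) * 0.04 - 0.02
  with_gd <- gdgf_filter(noisy, noisy, gdgf_params(radius = 4, lam = 0.5))
  without <- plain_wgif(noisy, 4, 0.5)
  edge_grad <- function(m) mean(abs(m[, 17] - m[, 16]))
  expect_gte(edge_grad(with_gd), edge_grad(without))
})
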