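test_that("shear filter banks form a partition of unity with the right symmetry", {
  for (l in 1:3) {
    W <- build_shear_filters(c(32, 48), l)
    expect_length(W, 2^l)
    S <- Reduce(`+`, W)
    expect_lt(max(abs(S - 1)), 1e-10)
    expect_true(all(vapply(W, function(w) all(w >= 0), TRUE)))
  }
  # conjugate symmetry w(u, v) = w(-u, -v) so impulse responses are real
  W <- build_shear_filters(c(64, 64), 2)
  flip <- function(w) {
    idx <- function(n) c(1, n:2)
    w[idx(nrow(w)), idx(ncol(w))]
  }
  for (w in W) expect_lt(max(abs(w - flip(w))), 1e-12)
})

test_that("each directional window dominates along its own wedge-center ray", {
  W <- build_shear_filters(c(64, 64), 2)
  # wedge centers on the shear coordinate: slopes -/+ 0.5 in each cone
  rays <- list(c(10, -5), c(10, 5), c(5, 10), c(-5, 10))  # (row freq, col freq)
  at_freq <- function(w, u, v) w[(u %% 64) + 1, (v %% 64) + 1]
  for (d in 1:4) {
    vals <- vapply(W, at_freq, 0, u = rays[[d]][1], v = rays[[d]][2])
    expect_equal(which.max(vals), d)
    expect_gt(vals[d], 0.9)
  }
  expect_error(build_shear_filters(c(4, 4), 1), "small")
})

test_that("the undecimated pyramid is exactly additive", {
  # impulse image: bands sum back to the impulse
  imp <- matrix(0, 32, 32); imp[16, 16] <- 1
  p <- pyramid_decompose(imp, 1)
  expect_lt(max(abs(p$low + p$bandpass[[1]] - imp)), 1e-8)
  # constant image: all bandpass energy vanishes, approximation keeps the DC
  p <- pyramid_decompose(matrix(0.7, 20, 20), 3)
  for (b in p$bandpass) expect_lt(max(abs(b)), 1e-8)
  expect_lt(max(abs(p$low - 0.7)), 1e-8)
  # random image: direct summation oracle
  x <- rand_img(32, 32, 21)
  p <- pyramid_decompose(x, 2)
  expect_lt(max(abs(p$low + Reduce(`+`, p$bandpass) - x)), 1e-8)
  expect_error(pyramid_decompose(matrix(c(1, Inf, 0, 0), 2), 1), "finite")
})

test_that("forward transform respects band counts and per-level directional sums", {
  x <- rand_img(32, 32, 31)
  cfg <- nsst_config(3, c(2, 3, 4))
  b <- nsst_forward(x, cfg)
  expect_equal(vapply(b$high, length, 0L), c(4L, 8L, 16L))
  # directional bands at each level sum to the pyramid bandpass band
  p <- pyramid_decompose(x, 3)
  for (k in 1:3) {
    expect_lt(max(abs(Reduce(`+`, b$high[[k]]) - p$bandpass[[k]])), 1e-8)
  }
  # constant image: high bands vanish
  bc <- nsst_forward(matrix(0.4, 32, 32), nsst_config(2, c(2, 2)))
  for (lev in bc$high) for (d in lev) expect_lt(max(abs(d)), 1e-8)
})

test_that("forward/inverse is perfect reconstruction across sizes and configs", {
  cases <- list(list(dim = c(64, 64), cfg = nsst_config(4, c(2, 2, 2, 2))),
                list(dim = c(33, 47), cfg = nsst_config(2, c(1, 3))),
                list(dim = c(40, 24), cfg = nsst_config(3, c(2, 2, 2))))
  for (cs in cases) {
    x <- rand_img(cs$dim[1], cs$dim[2], sum(cs$dim))
    rec <- pixels(nsst_inverse(nsst_forward(x, cs$cfg)))
    expect_lt(max(abs(rec - x)), 1e-6)
  }
  # zero sub-bands reconstruct to the zero image
  b <- nsst_forward(matrix(0, 16, 16), nsst_config(1, 1))
  expect_equal(max(abs(pixels(nsst_inverse(b)))), 0)
  # zeroing all high bands leaves exactly the low band
  imp <- matrix(0, 32, 32); imp[10, 20] <- 1
  b <- nsst_forward(imp, nsst_config(2, c(2, 2)))
  b$high <- lapply(b$high, function(lev) lapply(lev, function(m) m * 0))
  expect_lt(max(abs(pixels(nsst_inverse(b)) - b$low)), 1e-12)
})

test_that("the transform is linear and circular-shift covariant", {
  x <- rand_img(32, 32, 41); y <- rand_img(32, 32, 42)
  cfg <- nsst_config(2, c(2, 2))
  bx <- nsst_forward(x, cfg); by <- nsst_forward(y, cfg)
  bz <- nsst_forward(2 * x - 0.5 * y, cfg)
  expect_lt(max(abs(bz$low - (2 * bx$low - 0.5 * by$low))), 1e-10)
  for (k in 1:2) for (d in 1:4) {
    expect_lt(max(abs(bz$high[[k]][[d]] -
                        (2 * bx$high[[k]][[d]] - 0.5 * by$high[[k]][[d]]))), 1e-10)
  }
  shift <- function(m, s) m[c((s + 1):nrow(m), 1:s), c((s + 1):ncol(m), 1:s)]
  bs <- nsst_forward(shift(x, 5), cfg)
  expect_lt(max(abs(bs$low - shift(bx$low, 5))), 1e-10)
  for (k in 1:2) for (d in 1:4)
    expect_lt(max(abs(bs$high[[k]][[d]] - shift(bx$high[[k]][[d]], 5))), 1e-10)
})

test_that("invalid configurations and malformed band sets are rejected", {
  expect_error(nsst_config(0), "1..6")
  expect_error(nsst_config(2, c(2, 6)), "1..5")
  expect_error(nsst_config(3, c(2, 2)), "per level")
  b <- nsst_forward(rand_img(16, 16, 1), nsst_config(1, 2))
  b$high[[1]][[1]] <- matrix(0, 8, 8)
  expect_error(nsst_inverse(b), "shape")
  b2 <- nsst_forward(rand_img(16, 16, 1), nsst_config(1, 2))
  b2$high[[1]] <- b2$high[[1]][1:2]
  expect_error(nsst_inverse(b2), "expected")
})

test_that("sub-band serialization writes rasters plus a faithful manifest", {
  tmp <- withr::local_tempdir()
  b <- nsst_forward(rand_img(16, 16, 8), nsst_config(2, c(1, 2)))
  write_subbands(b, tmp)
  expect_true(file.exists(file.path(tmp, "low.tif")))
  expect_length(list.files(tmp, pattern = "^high_.*\\.tif$"), 2 + 4)
  man <- jsonlite::read_json(file.path(tmp, "manifest.json"), simplifyVector = TRUE)
  expect_equal(man$levels, 2)
  expect_equal(man$shear, c(1, 2))
  expect_equal(man$shape, c(16, 16))
})
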