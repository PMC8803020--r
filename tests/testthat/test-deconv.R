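test_that("FFT convolution matches the brute-force spatial oracle in 1D/2D/3D", {
  set.seed(21)
  a1 <- runif(17)
  k1 <- runif(5)
  expect_equal(convolve_fft(a1, k1), conv_brute_1d(a1, k1), tolerance = 1e-10)

  a2 <- matrix(runif(11 * 13), 11, 13)
  k2 <- matrix(runif(15), 3, 5)
  expect_equal(convolve_fft(a2, k2), conv_brute_2d(a2, k2), tolerance = 1e-10)

  a3 <- array(runif(9^3), c(9, 9, 9))
  k3 <- array(runif(27), c(3, 3, 3))
  expect_equal(convolve_fft(a3, k3), conv_brute_3d(a3, k3), tolerance = 1e-10)

  expect_error(convolve_fft(a2, k1), "dimensionality")
  expect_error(convolve_fft(a1, runif(4)), "odd")
})

test_that("convolution identities: impulse kernel and impulse data", {
  set.seed(22)
  a <- array(runif(7^3), c(7, 7, 7))
  imp <- array(0, c(3, 3, 3))
  imp[2, 2, 2] <- 1
  expect_equal(convolve_fft(a, imp), a, tolerance = 1e-12)

  d <- array(0, c(9, 9, 9))
  d[5, 5, 5] <- 1
  k <- array(runif(27), c(3, 3, 3))
  expect_equal(convolve_fft(d, k)[4:6, 4:6, 4:6], k, tolerance = 1e-12)
})

test_that("batched y-column convolution agrees with per-column convolution", {
  set.seed(23)
  vol <- array(runif(6 * 15 * 7), c(6, 15, 7))
  k <- runif(5)
  out <- convolve_y(vol, k)
  for (x in c(1, 4)) for (z in c(2, 7))
    expect_equal(out[x, , z], conv_brute_1d(vol[x, , z], k), tolerance = 1e-10)
})

test_that("one RL step reproduces the hand-evaluated 1D example", {
  e <- rep(1, 5)
  v <- c(0, 0, 3, 0, 0)
  f <- rep(1, 3) / 3
  # e*f = (2/3,1,1,1,2/3); ratio = (0,0,3,0,0); ratio*b = (0,1,1,1,0)
  expect_equal(rl_step(e, v, f, f), c(0, 1, 1, 1, 0), tolerance = 1e-10)
  expect_equal(rl_step(e, v, f, f), rl_step_brute_1d(e, v, f, f),
               tolerance = 1e-10)
  expect_error(rl_step(-e, v, f, f), "nonnegative")
})

test_that("delta projectors return the view; consistent data is a fixed point", {
  set.seed(24)
  est <- array(runif(6^3) + 0.5, c(6, 6, 6))
  view <- array(runif(6^3), c(6, 6, 6))
  imp <- array(0, c(3, 3, 3))
  imp[2, 2, 2] <- 1
  expect_equal(rl_step(est, view, imp, imp), view, tolerance = 1e-12)

  # interior-supported estimate, view generated by the forward model
  f <- make_gaussian_psf(c(1, 1, 1.5), radius = 5)
  e <- array(0, c(24, 24, 24))
  e[10:15, 10:15, 10:15] <- runif(6^3) + 0.1
  v <- convolve_fft(e, f)
  v[v < 0] <- 0
  e1 <- rl_step(e, v, f, f)   # symmetric PSF: mirrored b = f
  expect_lt(max(abs(e1 - e)) / max(e), 1e-8)
})

test_that("single-view RL approximately conserves flux for interior objects", {
  set.seed(25)
  f <- make_gaussian_psf(c(1.2, 1.2, 1.2), radius = 4)
  gt <- array(0, c(32, 32, 32))
  gt[13:20, 13:20, 13:20] <- runif(8^3)
  v <- convolve_fft(gt, f)
  v[v < 0] <- 0
  est <- v
  for (k in 1:5) {
    nxt <- rl_step(est, v, f, f)
    expect_lt(abs(sum(nxt) - sum(est)) / sum(est), 0.005)
    est <- nxt
  }
})

test_that("back projector construction: impulses, mirror, and Gaussian compound", {
  imp <- array(0, c(3, 3, 3))
  imp[2, 2, 2] <- 1
  for (opt in c("matched", "opt1", "opt2")) {
    pr <- make_backprojectors(list(imp, imp), opt)
    for (b in pr$backward)
      expect_equal(which(b == max(b)), (length(b) + 1) %/% 2)
  }

  # symmetric PSFs: matched back projector equals the forward one
  g <- make_gaussian_psf(c(1, 1, 2), radius = 6)
  prm <- make_backprojectors(list(g), "matched")
  expect_equal(prm$backward[[1]], prm$forward[[1]], tolerance = 1e-12)

  # opt2 compound of two 1D Gaussians is a Gaussian with combined variance
  s1 <- 1.5; s2 <- 2
  k1 <- dnorm(-9:9, sd = s1); k1 <- k1 / sum(k1)
  k2 <- dnorm(-9:9, sd = s2); k2 <- k2 / sum(k2)
  pr <- make_backprojectors(list(k1, k2), "opt2")
  b <- pr$backward[[1]]
  r <- (length(b) - 1) / 2
  ref <- dnorm(-r:r, sd = sqrt(s1^2 + s2^2))
  ref <- ref / sum(ref)
  expect_equal(b, ref, tolerance = 1e-4)
  expect_identical(pr$backward[[1]], pr$backward[[2]])

  expect_error(make_backprojectors(list(), "opt1"), "non-empty")
})

test_that("initial estimate is the view average", {
  v1 <- array(2, c(4, 4, 4))
  v2 <- array(4, c(4, 4, 4))
  expect_equal(init_estimate(list(v1, v2)), array(3, c(4, 4, 4)))
  expect_equal(init_estimate(list(v1)), v1)
})

test_that("mvd with one view and delta projectors returns the masked view", {
  set.seed(26)
  v <- matrix(runif(20^2), 20)
  imp <- matrix(0, 3, 3)
  imp[2, 2] <- 1
  pr <- make_backprojectors(list(imp), "matched")
  m <- binmask(list(v), blur_sigma = 2)
  out <- mvd(list(v), pr, weights = list(matrix(1, 20, 20)), mask = m,
             n_iter = 1)
  expect_equal(out, v * m * m, tolerance = 1e-10)
})

test_that("two identical views equal single-view RL under the fused update", {
  set.seed(27)
  f <- make_gaussian_psf(c(1, 1, 1.5), radius = 5)
  gt <- array(0, c(20, 20, 20))
  gt[8:13, 8:13, 8:13] <- runif(6^3)
  v <- convolve_fft(gt, f)
  v[v < 0] <- 0
  pr <- make_backprojectors(list(f, f), "matched")
  out2 <- mvd(list(v, v), pr, n_iter = 4)

  est <- init_estimate(list(v))
  for (k in 1:4) est <- rl_step(est, v, f, f)
  expect_lt(max(abs(out2 - est)) / max(est), 1e-8)
})

test_that("mvd is equivariant under view permutation and stays nonnegative", {
  fx <- list()
  set.seed(28)
  f1 <- make_gaussian_psf(c(1, 1, 2), radius = 6)
  f2 <- rotate_psf_to_view(f1, 90)
  gt <- array(0, c(24, 24, 24))
  gt[9:16, 9:16, 9:16] <- runif(8^3)
  v1 <- convolve_fft(gt, f1); v1[v1 < 0] <- 0
  v2 <- convolve_fft(gt, f2); v2[v2 < 0] <- 0
  w <- weights_intensity(list(v1, v2))
  pr <- make_backprojectors(list(f1, f2), "matched")
  out <- mvd(list(v1, v2), pr, w, n_iter = 3)

  pr_p <- make_backprojectors(list(f2, f1), "matched")
  out_p <- mvd(list(v2, v1), pr_p, w[c(2, 1)], n_iter = 3)
  expect_equal(out_p, out, tolerance = 1e-12)
  expect_true(min(out) >= 0)
})

test_that("slice blocking is pure scheduling: identical results", {
  fx <- clean_fixture(32L)
  psf2ds <- lapply(fx$psfs, extract_psf2d)
  c1 <- fusion_config(method = "2d", iters_mvd = 2, block_slices = 1)
  call <- fusion_config(method = "2d", iters_mvd = 2, block_slices = "auto")
  o1 <- mvd2d_slicewise(fx$views, psf2ds, c1)
  o2 <- mvd2d_slicewise(fx$views, psf2ds, call)
  expect_equal(o1, o2, tolerance = 1e-12)
})

test_that("capture returns per-iteration estimates consistent with the final", {
  fx <- clean_fixture(32L)
  psf2ds <- lapply(fx$psfs, extract_psf2d)
  cfg <- fusion_config(method = "2d", iters_mvd = 3)
  snaps <- mvd2d_slicewise(fx$views, psf2ds, cfg, capture = TRUE)
  final <- mvd2d_slicewise(fx$views, psf2ds, cfg)
  expect_length(snaps, 3)
  expect_equal(snaps[[3]], final, tolerance = 1e-12)
})

test_that("1D deconvolution: zero iterations is the identity, and it deblurs", {
  set.seed(29)
  vol <- array(0, c(12, 48, 12))
  vol[4:9, 16:32, 4:9] <- runif(6 * 17 * 6) * (runif(6 * 17 * 6) > 0.7)
  p1 <- dnorm(-8:8, sd = 2)
  p1 <- p1 / sum(p1)
  blurred <- convolve_y(vol, p1)
  blurred[blurred < 0] <- 0
  expect_identical(deconv1d(blurred, p1, n_iter = 0), blurred)
  out <- deconv1d(blurred, p1, n_iter = 10)
  expect_lt(mse(out, vol, gain = TRUE), mse(blurred, vol, gain = TRUE))
  expect_true(min(out) >= 0)
})

test_that("2d1d with zero 1D iterations reduces to plain 2d fusion", {
  fx <- clean_fixture(32L)
  cfg0 <- fusion_config(method = "2d1d", iters_mvd = 2, iters_1d = 0)
  cfg2 <- fusion_config(method = "2d", iters_mvd = 2)
  r0 <- fuse(fx$views, fx$psfs, cfg0)
  r2 <- fuse(fx$views, fx$psfs, cfg2)
  expect_identical(r0$estimate, r2$estimate)
})

test_that("fuse records per-iteration diagnostics against ground truth", {
  fx <- clean_fixture(32L)
  cfg <- fusion_config(method = "2d", iters_mvd = 3, backprojector = "matched")
  r <- fuse(fx$views, fx$psfs, cfg, gt = fx$gt)
  expect_equal(nrow(r$diagnostics), 3)
  expect_true(all(diff(r$diagnostics$mse) < 0))   # early iterations improve
  expect_true(all(r$diagnostics$pcc >= -1 & r$diagnostics$pcc <= 1))
})
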