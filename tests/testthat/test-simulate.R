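test_that("phantom generation is deterministic under a fixed seed", {
  a <- make_lines_phantom(32, n_lines = 10, seed = 3)
  b <- make_lines_phantom(32, n_lines = 10, seed = 3)
  expect_identical(a, b)
  c <- make_lines_phantom(32, n_lines = 10, seed = 4)
  expect_false(identical(a, c))
})

test_that("lines phantom: intensity range, body-only case, ray collinearity", {
  body <- make_lines_phantom(32, n_lines = 0, seed = 1)
  expect_equal(max(body), 1)
  ctr <- (32 + 1) / 2
  # content confined to the central body
  idx <- which(body > 0.5, arr.ind = TRUE)
  expect_true(all(sqrt(rowSums((idx - ctr)^2)) < 2 * 32 / 16 + 1))

  ph <- make_lines_phantom(48, n_lines = 6, seed = 7)
  expect_true(max(ph) <= 1 && min(ph) >= 0)
  dirs <- attr(ph, "directions")
  # every bright voxel outside the body lies within 1 voxel of some ray
  ctr <- (48 + 1) / 2
  vox <- which(ph > 0.4, arr.ind = TRUE)
  p <- sweep(vox, 2, c(ctr, ctr, ctr))
  r <- sqrt(rowSums(p^2))
  outside <- r > 48 / 16 * 2
  p <- p[outside, , drop = FALSE]
  dmin <- apply(p, 1, function(q) {
    min(apply(dirs, 1, function(u) {
      t <- sum(q * u)
      if (t < 0) Inf else sqrt(sum((q - t * u)^2))
    }))
  })
  expect_true(all(dmin <= 1))
})

test_that("bead phantom honors separation, margin, and conservation", {
  ph <- make_bead_phantom(64, n_beads = 8, min_separation = 15, seed = 2,
                          margin = 10)
  expect_equal(sum(ph$data), 8)
  expect_equal(nrow(ph$centers), 8)
  d <- as.matrix(dist(ph$centers))
  expect_true(all(d[upper.tri(d)] >= 15))
  expect_true(all(ph$centers >= 11 & ph$centers <= 54))

  one <- make_bead_phantom(40, n_beads = 1, seed = 1)
  expect_equal(sum(one$data), 1)
  expect_equal(one$data[one$centers[1, 1], one$centers[1, 2], one$centers[1, 3]], 1)
})

test_that("attenuation follows exponential depth decay from the camera face", {
  vol <- array(1, c(8, 8, 16))
  att <- attenuate(vol, axis = 3, direction = 1, length = 10)
  expect_equal(att[4, 4, 1], 1)                       # front face unchanged
  expect_equal(att[4, 4, 11], exp(-1), tolerance = 1e-12)  # depth = length
  expect_true(all(diff(att[1, 1, ]) < 0))

  rev_att <- attenuate(vol, axis = 3, direction = -1, length = 10)
  expect_equal(rev_att[2, 2, ], rev(att[2, 2, ]))

  near_id <- attenuate(vol, length = 1e6)
  expect_true(max(abs(near_id - vol)) <= 1e-3)
  expect_error(attenuate(vol, length = 0), "length")
})

test_that("noiseless identity limit: no PSF, no attenuation, no noise", {
  gt <- make_lines_phantom(32, n_lines = 5, seed = 9)
  params <- acquisition_params(attenuation_length = Inf,
                               psf = array(1, c(1, 1, 1)),
                               gaussian_variance = 0, photon_budget = Inf,
                               seed = 1)
  v <- simulate_view(gt, 90, params)
  expect_equal(v, gt, tolerance = 1e-12, ignore_attr = TRUE)

  mv <- simulate_multiview(gt, params)
  expect_length(mv$views, 4)
  for (v in mv$views)
    expect_equal(v, gt, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Gaussian noise component has the configured variance", {
  gt <- array(0.5, c(128, 128, 128))   # >= 1e6 voxels, far from clipping
  params <- acquisition_params(attenuation_length = Inf,
                               psf = array(1, c(1, 1, 1)),
                               gaussian_variance = 1.6e-5,
                               photon_budget = Inf, seed = 31)
  v <- simulate_view(gt, 0, params)
  expect_equal(var(as.vector(v - gt)), 1.6e-5, tolerance = 0.05)
  expect_equal(mean(v - gt), 0, tolerance = 1e-5)
})

test_that("averaging noisy realizations converges to the noiseless view", {
  gt <- array(0.3, c(12, 12, 12))
  clean_params <- acquisition_params(attenuation_length = Inf,
                                     psf = array(1, c(1, 1, 1)),
                                     gaussian_variance = 0,
                                     photon_budget = Inf, seed = 1)
  clean <- simulate_view(gt, 0, clean_params)
  reps <- vapply(1:100, function(i) {
    p <- acquisition_params(attenuation_length = Inf,
                            psf = array(1, c(1, 1, 1)),
                            gaussian_variance = 1e-4,
                            photon_budget = 500, seed = 100 + i)
    simulate_view(gt, 0, p)
  }, numeric(length(gt)))
  avg <- array(rowMeans(reps), dim(gt))
  rms_single <- sqrt(mean((reps[, 1] - as.vector(clean))^2))
  rms_avg <- sqrt(mean((avg - clean)^2))
  expect_lt(rms_avg, rms_single / 5)   # ~1/sqrt(100) scaling
})

test_that("opposing views carry mirrored attenuation gradients", {
  gt <- array(1, c(32, 32, 32))
  params <- acquisition_params(attenuation_length = 16,
                               psf = array(1, c(1, 1, 1)),
                               gaussian_variance = 0, photon_budget = Inf,
                               seed = 1)
  v0 <- simulate_view(gt, 0, params)
  v180 <- simulate_view(gt, 180, params)
  p0 <- log(apply(v0, 3, mean))
  p180 <- log(apply(v180, 3, mean))
  expect_lt(cor(p0, p180), 0)
  expect_equal(p0, rev(p180), tolerance = 1e-10)
})

test_that("per-view noise streams are independent but reproducible", {
  gt <- make_lines_phantom(32, n_lines = 5, seed = 9)
  params <- acquisition_params(attenuation_length = 16, seed = 77)
  mv1 <- simulate_multiview(gt, params)
  mv2 <- simulate_multiview(gt, params)
  expect_identical(mv1$views, mv2$views)
  expect_false(identical(mv1$views[[1]], mv1$views[[2]]))
  # rotated per-view PSFs accompany the views
  expect_equal(mv1$psfs[[2]], rotate_psf_to_view(normalize_psf(params$psf), 90))
})

test_that("degradations never increase total intensity", {
  gt <- make_lines_phantom(32, n_lines = 8, seed = 5)
  att <- attenuate(gt, 3, 1, 16)
  expect_lte(sum(att), sum(gt))
  blur <- convolve_fft(att, make_gaussian_psf())
  expect_lte(sum(blur), sum(att) * (1 + 1e-10))
})
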