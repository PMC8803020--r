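# Shared simulated fixtures, memoized so expensive ones are built once per
# test run. All stochastic fixtures are fully seeded.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# standard noisy 4-view lines-phantom fixture: attenuation length = half
# the extent, default PSF, photon budget 1000, Gaussian variance 1.6e-5
std_fixture <- function(extent = 64L, n_lines = if (extent >= 128L) 50L else 30L) {
  memo(paste0("std", extent), {
    gt <- make_lines_phantom(extent, n_lines = n_lines, seed = 1)
    params <- acquisition_params(attenuation_length = extent / 2, seed = 1001)
    sim <- simulate_multiview(gt, params)
    list(gt = gt, views = sim$views, psfs = sim$psfs, params = params)
  })
}

# noiseless, attenuation-free 4-view fixture (separable Gaussian PSF)
clean_fixture <- function(extent = 64L) {
  memo(paste0("clean", extent), {
    gt <- make_lines_phantom(extent, n_lines = 30L, seed = 1)
    params <- acquisition_params(attenuation_length = Inf,
                                 gaussian_variance = 0,
                                 photon_budget = Inf, seed = 1001)
    sim <- simulate_multiview(gt, params)
    list(gt = gt, views = sim$views, psfs = sim$psfs, params = params)
  })
}

# MSE/PCC curves of all three methods on the standard 128^3 fixture
std_curves_128 <- function() {
  memo("qc128", {
    fx <- std_fixture(128L)
    quality_curve(fx$views, fx$psfs, fx$gt, max_iters = 15L)
  })
}

# noiseless 4-view bead fixture plus fused volumes at default iterations
bead_fixture <- function(extent = 96L) {
  memo(paste0("beads", extent), {
    ph <- make_bead_phantom(extent, n_beads = 12L, min_separation = 24,
                            seed = 5, margin = 18L)
    params <- acquisition_params(attenuation_length = Inf,
                                 gaussian_variance = 0,
                                 photon_budget = Inf, seed = 2001)
    sim <- simulate_multiview(ph$data, params)
    fused <- lapply(c("2d", "2d1d", "3d"), function(m)
      fuse(sim$views, sim$psfs, fusion_config(method = m))$estimate)
    names(fused) <- c("2d", "2d1d", "3d")
    list(phantom = ph, views = sim$views, psfs = sim$psfs, fused = fused)
  })
}
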