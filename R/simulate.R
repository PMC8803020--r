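## Synthetic ground truth and multi-view acquisition simulator: a
## line-structure phantom (microtubule-like), sub-resolution bead phantoms,
## depth-dependent attenuation along the detection axis, anisotropic PSF
## blur, and Poisson + Gaussian noise.

# evaluate code under a fixed RNG seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Acquisition parameters for the multi-view simulator
#'
#' Defaults emulate a four-view light-sheet acquisition: views at 90-degree
#' steps about y, exponential intensity attenuation along each view's
#' detection axis, an anisotropic Gaussian detection PSF (lateral sigma
#' 1.05, axial sigma 5.2 voxels), shot noise with an expected photon budget
#' of 1000 photons at unit intensity, and additive zero-mean Gaussian
#' detector noise with variance 1.6e-5 on the `[0, 1]` intensity scale.
#'
#' @param angles view angles in degrees (multiples of 90)
#' @param attenuation_length exponential decay length in voxels; `NULL`
#'   (default) means half the volume extent, resolved at simulation time;
#'   `Inf` disables attenuation
#' @param psf 3D PSF array (odd extents); default anisotropic Gaussian
#' @param gaussian_variance detector noise variance on the `[0, 1]` scale
#' @param photon_budget expected photons at intensity 1; `Inf` disables
#'   shot noise
#' @param seed integer seed; view `i` uses stream `seed + i - 1`
#' @return an `acquisition_params` list
#' @export
acquisition_params <- function(angles = c(0, 90, 180, 270),
                               attenuation_length = NULL,
                               psf = make_gaussian_psf(),
                               gaussian_variance = 1.6e-5,
                               photon_budget = 1000,
                               seed = 1L) {
  if (!is.null(attenuation_length) && attenuation_length <= 0)
    stop("attenuation_length must be > 0")
  if (gaussian_variance < 0) stop("gaussian_variance must be >= 0")
  if (photon_budget <= 0) stop("photon_budget must be > 0")
  structure(list(angles = angles, attenuation_length = attenuation_length,
                 psf = psf, gaussian_variance = gaussian_variance,
                 photon_budget = photon_budget, seed = as.integer(seed)),
            class = "acquisition_params")
}

#' Line-structure ground-truth phantom
#'
#' Rays emanating from the volume center in uniformly random directions,
#' rasterized with an anti-aliased one-voxel-wide Gaussian cross profile
#' (peak 0.8), plus a brighter smooth central body (peak 1). Resembles
#' microtubules radiating from a mitotic spindle. Deterministic for a
#' fixed seed.
#'
#' @param extent cubic volume edge length in voxels, >= 32
#' @param n_lines number of rays
#' @param seed integer RNG seed
#' @return 3D array in `[0, 1]` with attribute `directions` (n_lines x 3
#'   matrix of unit ray directions)
#' @export
make_lines_phantom <- function(extent, n_lines = 50L, seed = 1L) {
  if (extent < 32L) stop("extent must be >= 32")
  ctr <- (extent + 1) / 2
  vol <- array(0, rep(as.integer(extent), 3L))
  sig <- 1 / (2 * sqrt(2 * log(2)))   # FWHM = 1 voxel
  dirs <- with_seed(seed, {
    z <- stats::runif(n_lines, -1, 1)
    phi <- stats::runif(n_lines, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    cbind(r * cos(phi), z, r * sin(phi))
  })
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  if (n_lines > 0L) for (i in seq_len(n_lines)) {
    u <- dirs[i, ]
    # distance from the center to the volume boundary along u
    tmax <- min(ifelse(abs(u) < 1e-12, Inf,
                       pmax((1 - ctr) / u, (extent - ctr) / u)))
    t <- seq(0, tmax, by = 0.3)
    p <- cbind(ctr + t * u[1], ctr + t * u[2], ctr + t * u[3])
    pr <- round(p)
    for (k in seq_len(nrow(offs))) {
      vox <- pr + matrix(offs[k, ], nrow(p), 3L, byrow = TRUE)
      keep <- vox[, 1] >= 1 & vox[, 1] <= extent &
              vox[, 2] >= 1 & vox[, 2] <= extent &
              vox[, 3] >= 1 & vox[, 3] <= extent
      if (!any(keep)) next
      vox <- vox[keep, , drop = FALSE]
      d2 <- rowSums((vox - p[keep, , drop = FALSE])^2)
      val <- 0.8 * exp(-d2 / (2 * sig^2))
      ord <- order(val)          # ascending: the largest write lands last
      idx <- vox[ord, 1] + (vox[ord, 2] - 1) * extent +
             (vox[ord, 3] - 1) * extent^2
      vol[idx] <- pmax(vol[idx], val[ord])
    }
  }
  # bright central body with a smooth super-Gaussian edge
  r0 <- extent / 16
  rng <- max(1, floor(ctr - 2 * r0)):min(extent, ceiling(ctr + 2 * r0))
  gx <- rng - ctr
  d2 <- outer(outer(gx^2, gx^2, `+`), gx^2, `+`)
  vol[rng, rng, rng] <- pmax(vol[rng, rng, rng], exp(-(sqrt(d2) / r0)^4))
  if (max(vol) > 0) vol <- vol / max(vol)   # unit peak for nonempty objects
  attr(vol, "directions") <- dirs
  vol
}

#' Sub-resolution bead phantom
#'
#' Single-voxel unit impulses at seeded random integer positions with a
#' minimum pairwise separation and an edge margin, mimicking an imaging
#' phantom of sub-diffraction fluorescent beads. True centers are returned
#' for validating detection and resolution metrics.
#'
#' @param extent cubic volume edge length in voxels
#' @param n_beads number of beads
#' @param min_separation minimum pairwise Euclidean distance in voxels
#' @param seed integer RNG seed
#' @param margin minimum distance of centers from the volume faces
#' @return list with `data` (3D array) and `centers` (n_beads x 3 matrix)
#' @export
make_bead_phantom <- function(extent, n_beads, min_separation = 20,
                              seed = 1L, margin = 16L) {
  lo <- margin + 1L
  hi <- extent - margin
  if (hi < lo) stop("margin too large for extent")
  centers <- with_seed(seed, {
    acc <- matrix(numeric(0), 0L, 3L)
    tries <- 0L
    while (nrow(acc) < n_beads) {
      if ((tries <- tries + 1L) > 10000L * max(1L, n_beads))
        stop("could not place beads with the requested separation")
      cand <- sample(lo:hi, 3L, replace = TRUE)
      if (nrow(acc) == 0L ||
          min(sqrt(rowSums((acc - matrix(cand, nrow(acc), 3L,
                                         byrow = TRUE))^2))) >= min_separation)
        acc <- rbind(acc, cand)
    }
    acc
  })
  vol <- array(0, rep(as.integer(extent), 3L))
  vol[centers[, 1] + (centers[, 2] - 1) * extent +
      (centers[, 3] - 1) * extent^2] <- 1
  list(data = vol, centers = unname(centers))
}

#' Depth-dependent intensity attenuation
#'
#' Multiplies the volume by `exp(-d / length)` where `d` is the depth in
#' voxels from the camera-facing face along the detection axis, modelling
#' scattering and absorption of the emitted fluorescence (Beer-Lambert
#' decay). Excitation-path attenuation is omitted (negligible for
#' two-sided illumination).
#'
#' @param vol 3D numeric array
#' @param axis detection axis (1 = x, 2 = y, 3 = z); default 3
#' @param direction `+1` if the camera faces the first-index face (depth
#'   grows with the index), `-1` for the opposite face
#' @param length decay length in voxels, > 0 (may be `Inf`)
#' @return attenuated volume
#' @export
attenuate <- function(vol, axis = 3L, direction = 1L, length = Inf) {
  if (length <= 0) stop("length must be > 0")
  d <- dim(vol)
  n <- d[axis]
  depth <- if (direction >= 0) seq_len(n) - 1 else rev(seq_len(n) - 1)
  fac <- exp(-depth / length)
  sweep(vol, axis, fac, `*`)
}

#' Simulate one view of a multi-view acquisition
#'
#' Rotates the ground truth into the view's frame (exact 90-degree
#' permutation), attenuates along the detection axis (z in the view frame,
#' camera at the first z face), convolves with the detection PSF, applies
#' Poisson shot noise (`counts ~ Poisson(photon_budget * I) /
#' photon_budget`) and additive Gaussian noise, clips at zero, and rotates
#' the result back into the common reference frame, so the delivered views
#' are registered.
#'
#' @param gt 3D ground-truth array in `[0, 1]` (cubic)
#' @param angle view angle in degrees, a multiple of 90
#' @param params acquisition parameters from [acquisition_params()]; the
#'   noise stream is seeded with `params$seed`
#' @return simulated view, same shape as `gt`
#' @export
simulate_view <- function(gt, angle, params = acquisition_params()) {
  len <- if (is.null(params$attenuation_length)) dim(gt)[3L] / 2
         else params$attenuation_length
  v <- rotate_about_y(gt, -angle)
  v <- attenuate(v, axis = 3L, direction = 1L, length = len)
  v <- convolve_fft(v, normalize_psf(params$psf))
  v[v < 0] <- 0
  with_seed(params$seed, {
    if (is.finite(params$photon_budget))
      v[] <- stats::rpois(length(v), params$photon_budget * v) /
        params$photon_budget
    if (params$gaussian_variance > 0)
      v <- v + stats::rnorm(length(v), 0, sqrt(params$gaussian_variance))
  })
  v[v < 0] <- 0
  rotate_about_y(v, angle)
}

#' Simulate a registered multi-view acquisition
#'
#' One simulated view per angle in `params$angles`, each with an
#' independent noise stream (seed offset by the view index), plus the
#' matching per-view PSFs (the base PSF rotated into each view's
#' orientation in the common frame).
#'
#' @param gt 3D ground-truth array (cubic)
#' @param params acquisition parameters from [acquisition_params()]
#' @return list with `views` (list of volumes) and `psfs` (list of 3D
#'   PSFs), both in the common reference frame
#' @export
simulate_multiview <- function(gt, params = acquisition_params()) {
  views <- vector("list", length(params$angles))
  psfs <- vector("list", length(params$angles))
  base <- normalize_psf(params$psf)
  for (i in seq_along(params$angles)) {
    p <- params
    p$seed <- params$seed + i - 1L
    views[[i]] <- simulate_view(gt, params$angles[i], p)
    psfs[[i]] <- rotate_psf_to_view(base, params$angles[i])
  }
  list(views = views, psfs = psfs)
}
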