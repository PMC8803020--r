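## Point spread function handling. A 3D PSF is a nonnegative array with odd
## extents (unambiguous center voxel). The 2D+1D scheme approximates it by
## its central x-z plane (perpendicular to the rotation axis y) plus its
## central column along y.

check_odd <- function(a) {
  d <- dimv(a)
  if (any(d %% 2L == 0L))
    stop("PSF must have odd extents, got ", paste(d, collapse = "x"))
  d
}

#' Normalize a PSF to unit sum
#'
#' Flux-preserving projectors require kernels summing to one; all
#' extraction and construction helpers in this package renormalize their
#' outputs.
#'
#' @param psf numeric vector/matrix/array, nonnegative, sum > 0
#' @return `psf / sum(psf)`
#' @export
normalize_psf <- function(psf) {
  s <- sum(psf)
  if (!is.finite(s) || s <= 0) stop("PSF must have positive finite sum")
  psf / s
}

#' Extract the central x-z plane of a 3D PSF
#'
#' Returns the plane perpendicular to the rotation axis (y) through the PSF
#' center, renormalized to unit sum. This is the 2D PSF used by slice-wise
#' 2D multi-view deconvolution.
#'
#' @param psf 3D numeric array with odd extents, `(x, y, z)`
#' @return 2D matrix `(x, z)`, sum = 1
#' @export
extract_psf2d <- function(psf) {
  d <- check_odd(psf)
  if (length(d) != 3L) stop("psf must be a 3D array")
  cy <- (d[2L] + 1L) %/% 2L
  normalize_psf(psf[, cy, ])
}

#' Extract the central column of a 3D PSF along the rotation axis
#'
#' Returns the 1D intensity profile of the PSF along the central line
#' parallel to the rotation axis (y), renormalized to unit sum. This is the
#' 1D PSF used by the deconvolution stage that follows 2D MVD.
#'
#' @param psf 3D numeric array with odd extents, `(x, y, z)`
#' @return numeric vector of length `dim(psf)[2]`, sum = 1
#' @export
extract_psf1d <- function(psf) {
  d <- check_odd(psf)
  if (length(d) != 3L) stop("psf must be a 3D array")
  cx <- (d[1L] + 1L) %/% 2L
  cz <- (d[3L] + 1L) %/% 2L
  normalize_psf(psf[cx, , cz])
}

#' Synthesize an anisotropic Gaussian 3D PSF
#'
#' Model PSF for simulations and tests: a separable Gaussian sampled at
#' voxel centers on a cubic grid of extent `2 * radius + 1`, normalized to
#' unit sum. The default widths (lateral sigma 1.05, axial sigma 5.2
#' voxels) mimic a light-sheet detection PSF with roughly 2.5 / 12 voxel
#' FWHM laterally / axially.
#'
#' @param sigma numeric length-3 vector of standard deviations (voxels) for
#'   the x, y, z axes, all > 0
#' @param radius integer support radius (voxels); must be at least
#'   `3 * max(sigma)` so that the truncated mass is negligible
#' @return 3D array of extent `2 * radius + 1` per axis, sum = 1
#' @export
make_gaussian_psf <- function(sigma = c(1.05, 1.05, 5.2), radius = NULL) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  if (length(sigma) != 3L || any(sigma <= 0))
    stop("sigma must be 3 positive values")
  if (is.null(radius)) radius <- ceiling(3 * max(sigma))
  if (radius < 3 * max(sigma))
    stop("support radius must be >= 3 * max(sigma)")
  g <- lapply(sigma, function(s) stats::dnorm(seq(-radius, radius), sd = s))
  psf <- outer(outer(g[[1]], g[[2]]), g[[3]])
  dim(psf) <- rep(2L * radius + 1L, 3L)
  normalize_psf(psf)
}

# one exact 90-degree rotation about the y axis (axis permutation + flip)
rot_y90 <- function(a) {
  b <- aperm(a, c(3L, 2L, 1L))
  b[rev(seq_len(dim(b)[1L])), , , drop = FALSE]
}

#' Rotate a volume about the rotation axis by a multiple of 90 degrees
#'
#' Exact rotation implemented as axis permutation and index reversal, with
#' no resampling; four successive 90-degree rotations are the identity.
#' Requires equal x and z extents (cubic volumes and PSF cubes satisfy
#' this).
#'
#' @param a 3D numeric array `(x, y, z)` with `dim(a)[1] == dim(a)[3]`
#' @param angle rotation angle in degrees, a multiple of 90
#' @return rotated array, same shape
#' @export
rotate_about_y <- function(a, angle) {
  if (length(dim(a)) != 3L) stop("a must be a 3D array")
  if (dim(a)[1L] != dim(a)[3L])
    stop("rotation about y requires equal x and z extents")
  if (abs(angle / 90 - round(angle / 90)) > 1e-9)
    stop("angle must be a multiple of 90 degrees")
  k <- ((round(angle / 90) %% 4L) + 4L) %% 4L
  while (k > 0L) {
    a <- rot_y90(a)
    k <- k - 1L
  }
  a
}

#' Rotate a PSF into a view's orientation
#'
#' Per-view PSFs of a multi-view acquisition with 90-degree steps are the
#' base detection PSF rotated about the rotation axis. The rotation is an
#' exact axis permutation/flip (see [rotate_about_y()]); the result is
#' renormalized.
#'
#' @param psf 3D PSF array with odd extents and equal x/z extents
#' @param angle view angle in degrees, a multiple of 90
#' @return rotated PSF, sum = 1
#' @export
rotate_psf_to_view <- function(psf, angle) {
  check_odd(psf)
  normalize_psf(rotate_about_y(psf, angle))
}
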