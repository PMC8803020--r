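## Per-pixel fusion weights (intensity or local-entropy based) and the
## apodization masks that roll intensities off smoothly at content edges to
## suppress FFT wrap artifacts.

check_views <- function(views) {
  if (!is.list(views) || length(views) == 0L)
    stop("views must be a non-empty list")
  d <- dimv(views[[1L]])
  for (v in views) {
    if (!identical(dimv(v), d)) stop("all views must have identical shapes")
    if (any(v < 0)) stop("views must be nonnegative")
  }
  d
}

#' Intensity-based fusion weights
#'
#' The weight of view v at pixel p is its fractional contribution to the
#' pixel intensity summed over all views. Where the intensity sum is zero
#' (no view has content) weights are uniform `1/N`.
#'
#' @param views non-empty list of same-shaped nonnegative arrays (2D slices
#'   or 3D volumes)
#' @return list of weight arrays, one per view, summing to 1 at every pixel
#' @export
weights_intensity <- function(views) {
  check_views(views)
  n <- length(views)
  total <- Reduce(`+`, views)
  zero <- total == 0
  total[zero] <- 1
  lapply(views, function(v) {
    w <- v / total
    w[zero] <- 1 / n
    w
  })
}

# sliding patch x patch box sums with symmetric mirror padding at borders
box_sum <- function(m, patch) {
  r <- (patch - 1L) %/% 2L
  n1 <- nrow(m)
  n2 <- ncol(m)
  if (r >= n1 || r >= n2) stop("patch too large for image")
  mp <- m[c(r:1, 1:n1, n1:(n1 - r + 1L)), c(r:1, 1:n2, n2:(n2 - r + 1L)),
          drop = FALSE]
  S1 <- apply(mp, 2L, cumsum)
  S2 <- t(apply(S1, 1L, cumsum))
  S <- matrix(0, nrow(mp) + 1L, ncol(mp) + 1L)
  S[-1L, -1L] <- S2
  i <- seq_len(n1)
  j <- seq_len(n2)
  S[i + patch, j + patch] - S[i, j + patch] - S[i + patch, j] + S[i, j]
}

# local entropy clamp: variances below 1/(2 pi e) would give negative H
.var_floor <- 1 / (2 * pi * exp(1))

#' Local entropy of an image
#'
#' Per-pixel entropy estimate `H = 1/2 * ln(2 * pi * e * sigma^2)` where
#' `sigma^2` is the population variance of the `patch_size x patch_size`
#' neighborhood (mirror-padded at the borders). The variance is clamped
#' below at `1/(2*pi*e)` so that `H >= 0`: flat patches get zero entropy
#' and the fractional-contribution weighting stays well defined.
#'
#' @param slice 2D numeric matrix
#' @param patch_size odd integer >= 3, neighborhood edge length in pixels
#' @return matrix of nonnegative entropies, same shape as `slice`
#' @export
local_entropy <- function(slice, patch_size = 11L) {
  if (!is.matrix(slice)) stop("slice must be a matrix")
  if (patch_size %% 2L == 0L || patch_size < 3L)
    stop("patch_size must be an odd integer >= 3")
  np <- patch_size^2
  m1 <- box_sum(slice, patch_size) / np
  m2 <- box_sum(slice^2, patch_size) / np
  v <- pmax(m2 - m1^2, 0)
  v <- pmax(v, .var_floor)
  0.5 * log(2 * pi * exp(1) * v)
}

#' Entropy-based fusion weights
#'
#' The weight of view v at pixel p is its fractional contribution to the
#' local entropy summed over all views — a contrast proxy that suppresses
#' views degraded by scattering and absorption. Pixels where all views have
#' zero (clamped) entropy get uniform weights `1/N`.
#'
#' @param views non-empty list of same-shaped nonnegative 2D matrices
#' @param patch_size odd neighborhood size for [local_entropy()]; default
#'   11 pixels
#' @return list of weight matrices summing to 1 at every pixel
#' @export
weights_entropy <- function(views, patch_size = 11L) {
  check_views(views)
  n <- length(views)
  ent <- lapply(views, local_entropy, patch_size = patch_size)
  total <- Reduce(`+`, ent)
  zero <- total == 0
  total[zero] <- 1
  lapply(ent, function(h) {
    w <- h / total
    w[zero] <- 1 / n
    w
  })
}

#' Content mask for a set of registered view slices
#'
#' Binary OR of the views' supports (pixels where at least one view is
#' positive), blurred with a Gaussian kernel so intensities and weights
#' roll off smoothly to zero at the content edges; this minimizes edge
#' artifacts in the FFT-based convolutions. The mask is applied
#' multiplicatively to data and weights.
#'
#' @param views non-empty list of same-shaped nonnegative 2D matrices
#' @param blur_sigma Gaussian standard deviation in pixels; default 20
#' @return matrix with values in `[0, 1]`
#' @export
binmask <- function(views, blur_sigma = 20) {
  check_views(views)
  content <- Reduce(`|`, lapply(views, function(v) v > 0))
  m <- gaussian_blur2d(matrix(as.numeric(content), nrow(content)), blur_sigma)
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

#' 1D apodization profile for deconvolution along the rotation axis
#'
#' Ones over the content range, zeros outside, blurred with a Gaussian so
#' the profile decays smoothly at the content ends; applied to every
#' y-column before 1D Richardson-Lucy deconvolution.
#'
#' @param length profile length (samples), >= 1
#' @param content_range integer vector `c(first, last)` of the content
#'   interval (1-based, inclusive)
#' @param sigma Gaussian standard deviation in pixels; default 5
#' @return numeric vector of `length` values in `[0, 1]`
#' @export
blend1d <- function(length, content_range = c(1L, length), sigma = 5) {
  if (length < 1L) stop("length must be >= 1")
  r <- as.integer(content_range)
  if (r[1L] < 1L || r[2L] > length || r[1L] > r[2L])
    stop("invalid content_range")
  x <- numeric(length)
  x[r[1L]:r[2L]] <- 1
  m <- gaussian_blur1d(x, sigma)
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}
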