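## FFT convolution machinery shared by all deconvolution paths.
## Convention: zero-padded *linear* convolution, output cropped to the input
## shape ("same"), kernel center at the middle voxel of its odd extents.

# dim() that also works for plain vectors (treated as 1D arrays)
dimv <- function(a) {
  d <- dim(a)
  if (is.null(d)) length(a) else d
}

#' Smallest FFT-friendly size >= n (prime factors <= 7)
#' @keywords internal
#' @noRd
next_fast_size <- function(n) {
  n <- as.integer(n)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L, 7L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# zero-pad an array into the lower corner of a grid of size `size`
pad_to <- function(a, size) {
  d <- dimv(a)
  nd <- length(size)
  if (nd == 1L) {
    out <- numeric(size)
    out[seq_len(d[1L])] <- a
  } else if (nd == 2L) {
    out <- matrix(0, size[1L], size[2L])
    out[seq_len(d[1L]), seq_len(d[2L])] <- a
  } else {
    out <- array(0, size)
    out[seq_len(d[1L]), seq_len(d[2L]), seq_len(d[3L])] <- a
  }
  out
}

crop_from <- function(a, start, len) {
  nd <- length(start)
  if (nd == 1L) {
    a[start[1L]:(start[1L] + len[1L] - 1L)]
  } else if (nd == 2L) {
    a[start[1L]:(start[1L] + len[1L] - 1L),
      start[2L]:(start[2L] + len[2L] - 1L), drop = FALSE]
  } else {
    a[start[1L]:(start[1L] + len[1L] - 1L),
      start[2L]:(start[2L] + len[2L] - 1L),
      start[3L]:(start[3L] + len[3L] - 1L), drop = FALSE]
  }
}

check_kernel <- function(kernel, ndim) {
  dk <- dimv(kernel)
  if (length(dk) != ndim)
    stop("kernel dimensionality (", length(dk),
         ") does not match data dimensionality (", ndim, ")")
  if (any(dk %% 2L == 0L))
    stop("kernel must have odd extents, got ", paste(dk, collapse = "x"))
  invisible(dk)
}

#' Build a reusable convolver for a fixed data shape and kernel
#'
#' Precomputes the kernel's optical transfer function on the zero-padded FFT
#' grid so that repeated convolutions of same-shaped data (as in iterative
#' Richardson-Lucy updates) cost two FFTs each instead of three.
#'
#' @param shape integer vector, the shape of the data to be convolved
#' @param kernel numeric vector/matrix/array with odd extents, same
#'   dimensionality as `shape`
#' @return a function `f(a)` returning the linear convolution of `a` with
#'   `kernel`, cropped to `shape`
#' @export
make_convolver <- function(shape, kernel) {
  shape <- as.integer(shape)
  dk <- check_kernel(kernel, length(shape))
  full <- shape + dk - 1L
  sz <- vapply(full, next_fast_size, integer(1))
  K <- stats::fft(pad_to(kernel, sz))
  start <- (dk + 1L) %/% 2L
  npts <- prod(sz)
  function(a) {
    if (!identical(as.integer(dimv(a)), shape))
      stop("data shape does not match convolver shape")
    A <- stats::fft(pad_to(a, sz))
    conv <- Re(stats::fft(A * K, inverse = TRUE)) / npts
    crop_from(conv, start, shape)
  }
}

#' Linear convolution via FFT
#'
#' Zero-padded linear convolution of `a` with an odd-extent kernel of the
#' same dimensionality (1D, 2D or 3D); the output has the shape of `a` with
#' the kernel centered at its middle element. Zero boundary conditions: the
#' data are embedded in a zero field of size `dim(a) + dim(kernel) - 1`
#' before transforming, so no circular wrap-around occurs.
#'
#' @param a numeric vector, matrix or 3D array
#' @param kernel numeric vector/matrix/array with odd extents
#' @return convolution result, same shape as `a`
#' @examples
#' convolve_fft(c(0, 0, 3, 0, 0), c(1, 1, 1) / 3)
#' @export
convolve_fft <- function(a, kernel) {
  make_convolver(dimv(a), kernel)(a)
}

#' Convolve every y-column of a volume with a 1D kernel
#'
#' Efficient batched 1D linear convolution along the rotation axis (y, the
#' second index) of a 3D volume, used by the 1D deconvolution stage.
#'
#' @param vol 3D numeric array `(x, y, z)`
#' @param kernel numeric vector of odd length
#' @return array of the same shape as `vol`
#' @export
convolve_y <- function(vol, kernel) {
  d <- dim(vol)
  if (length(d) != 3L) stop("vol must be a 3D array")
  K <- length(kernel)
  if (K %% 2L == 0L) stop("kernel must have odd length")
  ny <- d[2L]
  L <- next_fast_size(ny + K - 1L)
  m <- matrix(aperm(vol, c(2L, 1L, 3L)), nrow = ny)
  mp <- matrix(0, L, ncol(m))
  mp[seq_len(ny), ] <- m
  kf <- stats::fft(c(kernel, rep(0, L - K)))
  cf <- stats::mvfft(stats::mvfft(mp) * kf, inverse = TRUE)
  start <- (K + 1L) %/% 2L
  res <- Re(cf[start:(start + ny - 1L), , drop = FALSE]) / L
  aperm(array(res, c(ny, d[1L], d[3L])), c(2L, 1L, 3L))
}

# separable Gaussian blur of a matrix (zero boundary), used for masks
gaussian_blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  m <- convolve_fft(m, matrix(k, ncol = 1L))
  convolve_fft(m, matrix(k, nrow = 1L))
}

# Gaussian blur of a 1D profile (zero boundary)
gaussian_blur1d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  convolve_fft(x, k / sum(k))
}
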