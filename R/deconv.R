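## Richardson-Lucy multi-view deconvolution (MVD): the full-3D reference,
## the slice-wise 2D approximation, and the 2D+1D composition in which 2D
## MVD is followed by a cheap 1D deconvolution along the rotation axis.
##
## One RL iteration for a view computes e <- e * ((i / (e * f)) * b) with
## forward projector f and back projector b; a multi-view sweep fuses the
## per-view corrections c_v as their weighted average in one
## multiplicative step: e <- e * (1 - sum(w_v) + sum(w_v * c_v)).

# values of (e * f) below this are treated as zero and replaced by 1
# (divide-by-zero guard; intensities are O(1))
.rl_zero_guard <- 1e-12

# reverse a kernel along every axis (the "matched" back projector)
mirror_kernel <- function(k) {
  d <- dimv(k)
  if (length(d) == 1L) rev(k)
  else if (length(d) == 2L) k[rev(seq_len(d[1L])), rev(seq_len(d[2L])), drop = FALSE]
  else k[rev(seq_len(d[1L])), rev(seq_len(d[2L])), rev(seq_len(d[3L])), drop = FALSE]
}

# linear convolution of a list of centered odd kernels via FFT on the full
# support grid; result is centered and odd
conv_kernel_chain <- function(kernels) {
  ds <- lapply(kernels, dimv)
  nd <- length(ds[[1L]])
  full <- Reduce(`+`, ds) - (length(kernels) - 1L)
  sz <- vapply(full, next_fast_size, integer(1))
  F <- Reduce(`*`, lapply(kernels, function(k) stats::fft(pad_to(k, sz))))
  out <- Re(stats::fft(F, inverse = TRUE)) / prod(sz)
  out <- crop_from(out, rep(1L, nd), full)
  out[out < 0] <- 0
  out
}

# crop a centered kernel to the smallest odd box holding >= 1 - tol of its
# mass (per-axis marginal tails bounded by tol / ndim), then renormalize
crop_kernel_mass <- function(k, tol = 1e-6) {
  d <- dimv(k)
  nd <- length(d)
  k <- k / sum(k)
  radii <- integer(nd)
  for (a in seq_len(nd)) {
    marg <- if (nd == 1L) k else apply(k, a, sum)
    c0 <- (d[a] + 1L) %/% 2L
    r <- 0L
    while (sum(marg[max(1L, c0 - r):min(d[a], c0 + r)]) < 1 - tol / nd &&
           c0 + r < d[a]) r <- r + 1L
    radii[a] <- min(r, c0 - 1L)
  }
  ctr <- (d + 1L) %/% 2L
  out <- crop_from(k, ctr - radii, 2L * radii + 1L)
  normalize_psf(out)
}

#' Construct forward/back projector pairs for multi-view deconvolution
#'
#' The forward projector of each view is its (normalized) PSF. The back
#' projector depends on the chosen optimization:
#' \describe{
#'   \item{matched}{the axis-mirrored PSF of the same view (classical RL).}
#'   \item{opt1}{the mirrored PSF of the view convolved with the PSFs of
#'     all other views, renormalized — each view's update is spread into
#'     the directions the other views constrain.}
#'   \item{opt2}{a single compound kernel, the inverse transform of the
#'     product of all views' OTFs (equivalently the convolution of all
#'     PSFs), renormalized and shared by every view; shifts the quality
#'     optimum to the fewest iterations.}
#' }
#' Compound kernels are cropped to the smallest odd support retaining at
#' least `1 - 1e-6` of their mass to keep FFT grids small.
#'
#' @param psfs non-empty list of per-view kernels (all 1D, 2D or 3D, odd
#'   extents, common shape)
#' @param optimization one of `"matched"`, `"opt1"`, `"opt2"`
#' @return list with `forward` (list of kernels), `backward` (list of
#'   kernels, one per view) and `optimization`
#' @export
make_backprojectors <- function(psfs, optimization = c("opt2", "opt1", "matched")) {
  optimization <- match.arg(optimization)
  if (!is.list(psfs) || length(psfs) == 0L) stop("psfs must be a non-empty list")
  forward <- lapply(psfs, normalize_psf)
  for (f in forward) check_kernel(f, length(dimv(f)))
  n <- length(forward)
  backward <- switch(optimization,
    matched = lapply(forward, function(f) normalize_psf(mirror_kernel(f))),
    opt1 = lapply(seq_len(n), function(v) {
      ks <- c(list(mirror_kernel(forward[[v]])), forward[-v])
      if (length(ks) == 1L) normalize_psf(ks[[1L]])
      else crop_kernel_mass(conv_kernel_chain(ks))
    }),
    opt2 = {
      b <- if (n == 1L) normalize_psf(forward[[1L]])
           else crop_kernel_mass(conv_kernel_chain(forward))
      rep(list(b), n)
    })
  list(forward = forward, backward = backward, optimization = optimization)
}

#' One Richardson-Lucy update step
#'
#' Computes `e * ((view / (e * f)) * b)`. Entries of the blurred estimate
#' `e * f` that are (numerically) zero are replaced by 1 before the
#' division, and negative excursions of the FFT-computed correction are
#' floored at zero, so the output is nonnegative.
#'
#' @param est current estimate (nonnegative vector/matrix/array)
#' @param view observed image, same shape
#' @param f forward projector kernel (normalized, odd extents)
#' @param b back projector kernel (normalized, odd extents)
#' @return updated estimate, same shape
#' @export
rl_step <- function(est, view, f, b) {
  if (any(est < 0) || any(view < 0)) stop("est and view must be nonnegative")
  shape <- dimv(est)
  rl_step_conv(est, view, make_convolver(shape, f), make_convolver(shape, b))
}

rl_step_conv <- function(est, view, conv_f, conv_b) {
  denom <- conv_f(est)
  denom[denom < .rl_zero_guard] <- 1
  corr <- conv_b(view / denom)
  corr[corr < 0] <- 0
  est * corr
}

#' Initial fusion estimate by view averaging
#'
#' @param views non-empty list of same-shaped nonnegative arrays
#' @return element-wise mean of the views
#' @export
init_estimate <- function(views) {
  check_views(views)
  Reduce(`+`, views) / length(views)
}

# build per-view cached convolvers for a projector set; opt2's shared back
# projector gets a single convolver
make_mvd_convolvers <- function(shape, projectors) {
  cf <- lapply(projectors$forward, function(k) make_convolver(shape, k))
  if (projectors$optimization == "opt2") {
    cb1 <- make_convolver(shape, projectors$backward[[1L]])
    cb <- rep(list(cb1), length(projectors$backward))
  } else {
    cb <- lapply(projectors$backward, function(k) make_convolver(shape, k))
  }
  list(f = cf, b = cb)
}

#' Multi-view Richardson-Lucy deconvolution
#'
#' Runs `n_iter` sweeps of weighted multi-view RL starting from the view
#' average. In each sweep the per-view corrections
#' `c_v = (i_v / (e * f_v)) * b_v` are all computed from the current
#' estimate and fused as their weighted average,
#' `e <- e * sum_v(w_v * c_v)`, which reduces to plain RL for a single
#' view (and for any number of identical views) and lets a view with
#' `w_v = 0` at a pixel contribute nothing there. The content mask is
#' applied once to the input data and weights and once to the returned
#' estimate; where the masked weights sum to less than one (content
#' edges) the update is blended toward a no-op so apodization damps the
#' iteration instead of draining intensity. Works identically for 2D
#' slices and 3D volumes.
#'
#' @param views non-empty list of same-shaped nonnegative arrays
#' @param projectors projector set from [make_backprojectors()]
#' @param weights list of per-view weight arrays (see [weights_entropy()]);
#'   uniform `1/N` if `NULL`
#' @param mask content/apodization mask in `[0, 1]` (see [binmask()]);
#'   all-ones if `NULL`
#' @param n_iter number of sweeps, >= 1
#' @param capture if `TRUE`, return the (masked) estimate after every
#'   sweep as a list instead of only the final one
#' @param init optional starting estimate; defaults to the average of the
#'   (masked) views
#' @return final estimate (or list of per-iteration estimates)
#' @export
mvd <- function(views, projectors, weights = NULL, mask = NULL, n_iter = 1L,
                capture = FALSE, init = NULL) {
  d <- check_views(views)
  mvd_engine(views, projectors, weights, mask, n_iter, capture,
             make_mvd_convolvers(d, projectors), init = init)
}

mvd_engine <- function(views, projectors, weights, mask, n_iter, capture,
                       convolvers, init = NULL) {
  d <- dimv(views[[1L]])
  n <- length(views)
  if (is.null(weights)) {
    w1 <- array(1 / n, d)
    weights <- rep(list(w1), n)
  }
  if (!is.null(mask)) {
    views <- lapply(views, function(v) v * mask)
    weights <- lapply(weights, function(w) w * mask)
  }
  # where the masked weights sum to s < 1 (content edges), the update is
  # damped toward a no-op: e <- e * (1 - s + sum_v w_v c_v)
  wsum <- Reduce(`+`, weights)
  est <- if (is.null(init)) init_estimate(views) else init
  snaps <- if (capture) vector("list", n_iter)
  for (k in seq_len(n_iter)) {
    fused <- 1 - wsum
    for (v in seq_len(n)) {
      denom <- convolvers$f[[v]](est)
      denom[denom < .rl_zero_guard] <- 1
      corr <- convolvers$b[[v]](views[[v]] / denom)
      corr[corr < 0] <- 0
      fused <- fused + weights[[v]] * corr
    }
    est <- est * fused
    if (capture)
      snaps[[k]] <- if (is.null(mask)) est else est * mask
  }
  if (capture) snaps
  else if (is.null(mask)) est
  else est * mask
}

# resolve the "auto" back projector choice for a concrete method
resolve_backprojector <- function(config, method) {
  if (config$backprojector != "auto") config$backprojector
  else if (method == "3d") "matched"
  else "opt2"
}

# split 1..n into consecutive blocks of size `block` ("auto" = all at once)
slice_blocks <- function(n, block) {
  if (identical(block, "auto") || is.null(block)) block <- n
  block <- max(1L, as.integer(block))
  split(seq_len(n), ceiling(seq_len(n) / block))
}

#' Slice-wise 2D multi-view deconvolution
#'
#' Applies 2D MVD independently to every x-z plane (perpendicular to the
#' rotation axis y) of the registered views: per slice, fusion weights and
#' the content mask are computed from the input views, then [mvd()] runs
#' with the per-view 2D PSFs. Slices are processed in blocks of
#' `config$block_slices`; blocking is a scheduling concern only and does
#' not change the result.
#'
#' @param views non-empty list of registered, same-shaped 3D volumes
#' @param psf2ds list of per-view 2D PSFs (x-z plane), or a single matrix
#'   used for all views
#' @param config fusion configuration from [fusion_config()]
#' @param capture if `TRUE`, return per-iteration volumes as a list
#' @return fused 3D volume (or list of per-iteration volumes)
#' @export
mvd2d_slicewise <- function(views, psf2ds, config = fusion_config(),
                            capture = FALSE) {
  d <- check_views(views)
  if (length(d) != 3L) stop("views must be 3D volumes")
  n <- length(views)
  if (is.matrix(psf2ds)) psf2ds <- rep(list(psf2ds), n)
  if (length(psf2ds) != n) stop("need one 2D PSF per view")
  n_iter <- config$iters_mvd
  projectors <- make_backprojectors(psf2ds, resolve_backprojector(config, "2d"))
  convolvers <- make_mvd_convolvers(d[c(1L, 3L)], projectors)
  out <- if (capture) lapply(seq_len(n_iter), function(k) array(0, d))
         else array(0, d)
  for (block in slice_blocks(d[2L], config$block_slices)) {
    for (y in block) {
      slices <- lapply(views, function(v) v[, y, ])
      w <- switch(config$weighting,
                  intensity = weights_intensity(slices),
                  entropy = weights_entropy(slices, config$patch_size))
      m <- binmask(slices, config$mask_sigma2d)
      res <- mvd_engine(slices, projectors, w, m, n_iter, capture, convolvers)
      if (capture) {
        for (k in seq_len(n_iter)) out[[k]][, y, ] <- res[[k]]
      } else {
        out[, y, ] <- res
      }
    }
  }
  out
}

#' 1D Richardson-Lucy deconvolution along the rotation axis
#'
#' The second stage of 2D+1D MVD: every (x, z) column of the volume is
#' deconvolved along y with the 1D PSF (forward) and its mirror (back
#' projector). Columns are apodized with a [blend1d()] mask built from the
#' volume's content range along y before deconvolution. `n_iter = 0`
#' returns the volume unchanged.
#'
#' @param volume 3D numeric array `(x, y, z)`
#' @param psf1d 1D PSF along y (odd length; renormalized internally)
#' @param n_iter number of RL iterations, >= 0; default 3
#' @param blend_sigma Gaussian sigma (pixels) of the apodization mask;
#'   default 5
#' @return deconvolved volume, same shape
#' @export
deconv1d <- function(volume, psf1d, n_iter = 3L, blend_sigma = 5) {
  d <- dim(volume)
  if (length(d) != 3L) stop("volume must be a 3D array")
  if (n_iter == 0L) return(volume)
  f <- normalize_psf(psf1d)
  if (length(f) %% 2L == 0L) stop("psf1d must have odd length")
  ys <- which(apply(volume > 0, 2L, any))
  if (length(ys) == 0L) return(volume)
  mask <- blend1d(d[2L], range(ys), blend_sigma)
  mrep <- rep(mask, each = d[1L])   # broadcast along x, recycled over z
  data <- volume * mrep
  b <- rev(f)
  est <- data
  for (k in seq_len(n_iter)) {
    denom <- convolve_y(est, f)
    denom[denom < .rl_zero_guard] <- 1
    corr <- convolve_y(data / denom, b)
    corr[corr < 0] <- 0
    est <- est * corr
  }
  est
}

#' Fusion configuration
#'
#' Collects the tunable parameters of the MVD variants. Defaults follow
#' the recommended operating point: five 2D MVD iterations, three
#' additional 1D iterations for 2D+1D, eight iterations for 3D MVD,
#' entropy weighting with an 11x11 patch, the compound (`opt2`) back
#' projector, mask sigmas of 20 (2D content mask) and 5 (1D apodization)
#' pixels.
#'
#' @param method fusion method: `"2d1d"`, `"2d"` or `"3d"`
#' @param iters_mvd MVD sweep count; if `NULL`, 5 for 2d/2d1d and 8 for 3d
#' @param iters_1d 1D deconvolution iterations (2d1d only); default 3
#' @param weighting `"entropy"` or `"intensity"`
#' @param patch_size odd entropy patch edge (pixels); default 11
#' @param backprojector `"auto"` (default), `"opt2"`, `"opt1"` or
#'   `"matched"`; `"auto"` resolves to the accelerated compound `"opt2"`
#'   for the 2d/2d1d methods and to classical `"matched"` projectors for
#'   the 3d reference
#' @param mask_sigma2d Gaussian sigma of the 2D content mask; default 20
#' @param mask_sigma1d Gaussian sigma of the 1D apodization mask; default 5
#' @param block_slices slices per processing block, or `"auto"`
#' @param seed integer seed echoed into run reports
#' @return a `fusion_config` list
#' @export
fusion_config <- function(method = c("2d1d", "2d", "3d"), iters_mvd = NULL,
                          iters_1d = 3L,
                          weighting = c("entropy", "intensity"),
                          patch_size = 11L,
                          backprojector = c("auto", "opt2", "opt1", "matched"),
                          mask_sigma2d = 20, mask_sigma1d = 5,
                          block_slices = "auto", seed = 1L) {
  method <- match.arg(method)
  weighting <- match.arg(weighting)
  backprojector <- match.arg(backprojector)
  if (is.null(iters_mvd)) iters_mvd <- if (method == "3d") 8L else 5L
  if (iters_mvd < 1L) stop("iters_mvd must be >= 1")
  if (iters_1d < 0L) stop("iters_1d must be >= 0")
  if (patch_size %% 2L == 0L) stop("patch_size must be odd")
  structure(list(method = method, iters_mvd = as.integer(iters_mvd),
                 iters_1d = as.integer(iters_1d), weighting = weighting,
                 patch_size = as.integer(patch_size),
                 backprojector = backprojector,
                 mask_sigma2d = mask_sigma2d, mask_sigma1d = mask_sigma1d,
                 block_slices = block_slices, seed = as.integer(seed)),
            class = "fusion_config")
}

# assemble per-view 3D weight fields and a 3D mask by applying the 2D
# definitions to every y-slice (so 2D and 3D variants share identical
# in-plane weighting/masking); the mask is additionally apodized along y
# with the blend1d profile because the 3D convolutions also see the
# y-boundaries (the slice-wise variants never transform along y)
weights_and_mask_3d <- function(views, config) {
  d <- dimv(views[[1L]])
  n <- length(views)
  wfields <- lapply(seq_len(n), function(v) array(0, d))
  mfield <- array(0, d)
  for (y in seq_len(d[2L])) {
    slices <- lapply(views, function(v) v[, y, ])
    w <- switch(config$weighting,
                intensity = weights_intensity(slices),
                entropy = weights_entropy(slices, config$patch_size))
    for (v in seq_len(n)) wfields[[v]][, y, ] <- w[[v]]
    mfield[, y, ] <- binmask(slices, config$mask_sigma2d)
  }
  ys <- which(apply(mfield > 0, 2L, any))
  if (length(ys) > 0L) {
    by <- blend1d(d[2L], range(ys), config$mask_sigma1d)
    mfield <- mfield * rep(by, each = d[1L])
  }
  list(weights = wfields, mask = mfield)
}

#' Fuse registered multi-view volumes
#'
#' Dispatches on `config$method`: slice-wise 2D MVD (`"2d"`), 2D MVD
#' followed by 1D deconvolution along the rotation axis (`"2d1d"`), or
#' full-volume 3D MVD (`"3d"`). The 2D and 1D PSFs of the approximate
#' methods are extracted from the supplied 3D PSFs as central planes and
#' columns; the 1D PSF along the rotation axis is shared by all views
#' (rotation about y leaves the y profile unchanged).
#'
#' @param views non-empty list of registered, same-shaped, nonnegative 3D
#'   volumes with the rotation axis along y
#' @param psfs list of per-view 3D PSFs, or a single 3D PSF used for all
#'   views
#' @param config fusion configuration from [fusion_config()]
#' @param gt optional ground-truth volume; when supplied, per-iteration
#'   MSE/PCC diagnostics are recorded
#' @return list with `estimate` (fused volume), `config`, and
#'   `diagnostics` (data frame of per-iteration MSE/PCC, or `NULL`)
#' @export
fuse <- function(views, psfs, config = fusion_config(), gt = NULL) {
  d <- check_views(views)
  if (length(d) != 3L) stop("views must be 3D volumes")
  n <- length(views)
  if (!is.list(psfs)) psfs <- rep(list(psfs), n)
  if (length(psfs) != n) stop("need one PSF per view (or a single PSF)")
  capture <- !is.null(gt)

  if (config$method %in% c("2d", "2d1d")) {
    psf2ds <- lapply(psfs, extract_psf2d)
    res <- mvd2d_slicewise(views, psf2ds, config, capture = capture)
    if (config$method == "2d1d" && config$iters_1d > 0L) {
      psf1d <- extract_psf1d(psfs[[1L]])
      if (capture) res <- lapply(res, deconv1d, psf1d = psf1d,
                                 n_iter = config$iters_1d,
                                 blend_sigma = config$mask_sigma1d)
      else res <- deconv1d(res, psf1d, config$iters_1d, config$mask_sigma1d)
    }
  } else {
    wm <- weights_and_mask_3d(views, config)
    projectors <- make_backprojectors(lapply(psfs, normalize_psf),
                                      resolve_backprojector(config, "3d"))
    res <- mvd(views, projectors, wm$weights, wm$mask,
               n_iter = config$iters_mvd, capture = capture)
  }

  if (capture) {
    diag <- data.frame(
      method = config$method,
      iteration = seq_along(res),
      mse = vapply(res, mse, numeric(1), b = gt),
      pcc = vapply(res, pcc, numeric(1), b = gt))
    list(estimate = res[[length(res)]], config = config, diagnostics = diag)
  } else {
    list(estimate = res, config = config, diagnostics = NULL)
  }
}
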