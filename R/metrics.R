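## Quantitative evaluation: MSE/PCC against ground truth across iterations,
## and bead-based resolution analysis (detection, per-axis FWHM, cumulative
## normal fitting).

#' Mean squared error between two grids
#'
#' With `gain = TRUE` the first grid is rescaled by the least-squares gain
#' `sum(a*b) / sum(a*a)` before comparison — deconvolution does not fix the
#' absolute intensity scale, so quality curves against ground truth use the
#' gain-normalized form. The default is the plain (symmetric) MSE.
#'
#' @param a,b numeric arrays of identical shape
#' @param gain if `TRUE`, scale `a` to `b` by least-squares gain first
#' @return mean of squared differences
#' @export
mse <- function(a, b, gain = FALSE) {
  if (!identical(dimv(a), dimv(b))) stop("a and b must have the same shape")
  if (gain) {
    ss <- sum(a * a)
    if (ss > 0) a <- a * (sum(a * b) / ss)
  }
  mean((a - b)^2)
}

#' Pearson correlation coefficient between two grids
#'
#' Scale-free fusion quality metric; undefined (error) when either grid
#' has zero variance.
#'
#' @param a,b numeric arrays of identical shape
#' @return correlation in `[-1, 1]`
#' @export
pcc <- function(a, b) {
  if (!identical(dimv(a), dimv(b))) stop("a and b must have the same shape")
  a <- as.vector(a)
  b <- as.vector(b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("PCC undefined for zero-variance input")
  stats::cor(a, b)
}

# logical array marking voxels >= all 26 neighbors (borders padded -Inf)
local_maxima3d <- function(vol) {
  d <- dim(vol)
  ok <- array(TRUE, d)
  ix <- seq_len(d[1]); iy <- seq_len(d[2]); iz <- seq_len(d[3])
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sh <- array(-Inf, d)
    sx <- ix + dx; sy <- iy + dy; sz <- iz + dz
    vx <- sx >= 1 & sx <= d[1]; vy <- sy >= 1 & sy <= d[2]
    vz <- sz >= 1 & sz <= d[3]
    sh[ix[vx], iy[vy], iz[vz]] <- vol[sx[vx], sy[vy], sz[vz]]
    ok <- ok & (vol >= sh)
  }
  ok
}

#' Detect bead centers as pruned local intensity maxima
#'
#' Finds voxels that are local maxima over their 26-neighborhood and
#' exceed `threshold * max(volume)`, then greedily prunes them so that all
#' pairwise distances are at least `min_separation`, keeping the brightest
#' (ties broken by lexicographic coordinate order).
#'
#' @param volume 3D numeric array
#' @param threshold fraction of the volume maximum in `(0, 1)`
#' @param min_separation minimum pairwise distance in voxels
#' @return integer matrix with one `(x, y, z)` center per row (0 rows if
#'   the volume is empty)
#' @export
detect_beads <- function(volume, threshold = 0.3, min_separation = 10) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  mx <- max(volume)
  if (mx <= 0) return(matrix(integer(0), 0L, 3L))
  cand <- which(local_maxima3d(volume) & volume > threshold * mx,
                arr.ind = TRUE)
  if (nrow(cand) == 0L) return(matrix(integer(0), 0L, 3L))
  val <- volume[cand]
  ord <- order(-val, cand[, 1], cand[, 2], cand[, 3])
  cand <- cand[ord, , drop = FALSE]
  kept <- matrix(numeric(0), 0L, 3L)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(kept) == 0L ||
        min(rowSums((kept - matrix(p, nrow(kept), 3L, byrow = TRUE))^2)) >=
        min_separation^2)
      kept <- rbind(kept, p)
  }
  unname(kept)
}

#' Full width at half maximum of a spot profile along one axis
#'
#' Extracts the 1D intensity profile through `center` along the given
#' axis (up to `radius` voxels to each side, capped at the volume bounds),
#' subtracts the profile minimum as local background, and finds the
#' half-maximum crossings on both sides of the peak by linear interpolation
#' between bracketing samples.
#'
#' @param volume 3D numeric array
#' @param center numeric length-3 voxel position `(x, y, z)`
#' @param axis 1 (x), 2 (y) or 3 (z)
#' @param voxel voxel edge length (micrometers); default 1 (voxel units)
#' @param radius profile half-length in voxels; default 24
#' @return FWHM in micrometers, or `NA` if no half-maximum crossing exists
#'   on either side (profile clipped at the volume edge)
#' @export
measure_fwhm <- function(volume, center, axis, voxel = 1, radius = 24L) {
  d <- dim(volume)
  center <- round(center)
  c0 <- center[axis]
  lo <- max(1L, c0 - radius)
  hi <- min(d[axis], c0 + radius)
  idx <- lo:hi
  prof <- switch(axis,
                 volume[idx, center[2], center[3]],
                 volume[center[1], idx, center[3]],
                 volume[center[1], center[2], idx])
  prof <- prof - min(prof)
  pk <- which.max(prof)
  half <- prof[pk] / 2
  if (half <= 0) return(NA_real_)
  # left crossing
  left <- NA_real_
  if (pk > 1L) for (i in (pk - 1L):1L) {
    if (prof[i] < half) {
      left <- i + (half - prof[i]) / (prof[i + 1L] - prof[i])
      break
    }
  }
  right <- NA_real_
  if (pk < length(prof)) for (i in (pk + 1L):length(prof)) {
    if (prof[i] < half) {
      right <- i - (half - prof[i]) / (prof[i - 1L] - prof[i])
      break
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  (right - left) * voxel
}

#' Fit a cumulative normal to sorted samples
#'
#' Least-squares fit of `pnorm((x - mu) / sigma)` to the empirical
#' cumulative fraction at the sorted sample points; the reported standard
#' error of `mu` comes from the fit's parameter covariance. Falls back to
#' the sample mean and its standard error (flagged `converged = FALSE`)
#' when the fit cannot converge, e.g. for (near-)degenerate samples.
#'
#' @param samples numeric vector of at least 5 measurements
#' @return list with `mean`, `se` and `converged`
#' @export
fit_cumulative_normal <- function(samples) {
  n <- length(samples)
  if (n < 5L) stop("need at least 5 samples")
  xs <- sort(samples)
  p <- (seq_len(n) - 0.5) / n
  m0 <- mean(xs)
  s0 <- stats::sd(xs)
  fallback <- list(mean = m0, se = s0 / sqrt(n), converged = FALSE)
  if (!is.finite(s0) || s0 < 1e-12 * max(1, abs(m0))) return(fallback)
  fit <- tryCatch(
    stats::nls(p ~ stats::pnorm(xs, m, s),
               start = list(m = m0, s = s0),
               algorithm = "port", lower = c(-Inf, 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback)
  co <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  if (is.null(co)) return(fallback)
  list(mean = unname(co["m", "Estimate"]), se = unname(co["m", "Std. Error"]),
       converged = TRUE)
}

#' Per-axis bead FWHM summary of a volume
#'
#' End-to-end bead resolution analysis: detect beads, measure per-axis
#' FWHM for each, reject beads whose profile has no half-maximum crossing,
#' and summarize each axis by a cumulative-normal fit of the FWHM samples
#' (mean and standard error). When fewer than 5 beads survive, the sample
#' mean and its standard error are reported.
#'
#' @param volume 3D numeric array
#' @param voxel voxel edge length (micrometers)
#' @param threshold,min_separation passed to [detect_beads()]
#' @param radius profile half-length passed to [measure_fwhm()]
#' @return data frame with one row per axis: `axis`, `mean_fwhm`, `se`,
#'   `n_beads`
#' @export
bead_summary <- function(volume, voxel = 1, threshold = 0.3,
                         min_separation = 10, radius = 24L) {
  centers <- detect_beads(volume, threshold, min_separation)
  if (nrow(centers) == 0L) stop("no beads detected")
  out <- lapply(1:3, function(ax) {
    w <- apply(centers, 1L, function(p)
      measure_fwhm(volume, p, ax, voxel, radius))
    w <- w[!is.na(w)]
    if (length(w) >= 5L) {
      f <- fit_cumulative_normal(w)
      data.frame(axis = c("x", "y", "z")[ax], mean_fwhm = f$mean, se = f$se,
                 n_beads = length(w))
    } else {
      data.frame(axis = c("x", "y", "z")[ax], mean_fwhm = mean(w),
                 se = stats::sd(w) / sqrt(length(w)), n_beads = length(w))
    }
  })
  do.call(rbind, out)
}

#' MSE/PCC quality curves across iteration counts
#'
#' Runs the requested fusion methods for `1..max_iters` MVD iterations on
#' a simulated multi-view dataset and records the gain-normalized MSE and
#' the PCC against ground truth after every iteration. For `"2d1d"`, the
#' fixed number of 1D iterations (`config$iters_1d`) is appended to the 2D
#' result of every iteration depth, so its iteration index counts 2D
#' sweeps. The 2D sweeps are shared between the `"2d"` and `"2d1d"`
#' curves.
#'
#' @param views list of registered view volumes
#' @param psfs list of per-view 3D PSFs (or a single PSF)
#' @param gt ground-truth volume
#' @param methods subset of `c("2d", "2d1d", "3d")`
#' @param max_iters maximum iteration count; default 15
#' @param config fusion configuration (weighting, back projector, 1D
#'   iteration count, mask sigmas)
#' @return data frame with columns `method`, `iteration`, `mse`, `pcc`
#' @export
quality_curve <- function(views, psfs, gt,
                          methods = c("2d", "2d1d", "3d"),
                          max_iters = 15L, config = fusion_config()) {
  methods <- match.arg(methods, several.ok = TRUE)
  n <- length(views)
  if (!is.list(psfs)) psfs <- rep(list(psfs), n)
  rows <- list()
  record <- function(method, snaps) {
    data.frame(method = method, iteration = seq_along(snaps),
               mse = vapply(snaps, mse, numeric(1), b = gt, gain = TRUE),
               pcc = vapply(snaps, pcc, numeric(1), b = gt))
  }
  if (any(c("2d", "2d1d") %in% methods)) {
    cfg2 <- config
    cfg2$method <- "2d"
    cfg2$iters_mvd <- as.integer(max_iters)
    snaps2d <- mvd2d_slicewise(views, lapply(psfs, extract_psf2d), cfg2,
                               capture = TRUE)
    if ("2d" %in% methods) rows <- c(rows, list(record("2d", snaps2d)))
    if ("2d1d" %in% methods) {
      psf1d <- extract_psf1d(psfs[[1L]])
      snaps21 <- lapply(snaps2d, deconv1d, psf1d = psf1d,
                        n_iter = config$iters_1d,
                        blend_sigma = config$mask_sigma1d)
      rows <- c(rows, list(record("2d1d", snaps21)))
    }
  }
  if ("3d" %in% methods) {
    wm <- weights_and_mask_3d(views, config)
    projectors <- make_backprojectors(lapply(psfs, normalize_psf),
                                      resolve_backprojector(config, "3d"))
    snaps3d <- mvd(views, projectors, wm$weights, wm$mask,
                   n_iter = as.integer(max_iters), capture = TRUE)
    rows <- c(rows, list(record("3d", snaps3d)))
  }
  do.call(rbind, rows)
}
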