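## Preprocessing of raw anisotropic acquisitions: dark-offset subtraction,
## axial interpolation to isotropic voxels, zero-padding to cubic shape.
## Raw stacks are (x, y, z) arrays with z the acquisition (detection) axis;
## lateral sampling voxel_xy is finer than the axial step step_z.

#' Subtract a camera dark image from every slice of a stack
#'
#' Removes the fixed camera offset measured in a dark acquisition. The
#' result is clipped at zero so that downstream Poisson/Richardson-Lucy
#' assumptions (nonnegative intensities) hold.
#'
#' @param data 3D numeric array `(x, y, z)` of camera counts
#' @param dark 2D numeric matrix with the slice shape `(x, y)`
#' @return array of `data`'s shape with `pmax(data - dark, 0)` per slice
#' @export
subtract_dark <- function(data, dark) {
  d <- dim(data)
  if (length(d) != 3L) stop("data must be a 3D array")
  if (!is.matrix(dark) || !identical(dim(dark), d[1:2]))
    stop("dark image shape ", paste(dimv(dark), collapse = "x"),
         " does not match slice shape ", paste(d[1:2], collapse = "x"))
  out <- data - as.vector(dark)   # dark recycles over z (column-major)
  out[out < 0] <- 0
  out
}

# Keys cubic-convolution interpolation kernel (a = -0.5), the standard
# "bicubic" resampling kernel; reproduces linear ramps exactly.
keys_weight <- function(s, a = -0.5) {
  s <- abs(s)
  w <- numeric(length(s))
  i1 <- s <= 1
  w[i1] <- (a + 2) * s[i1]^3 - (a + 3) * s[i1]^2 + 1
  i2 <- s > 1 & s < 2
  w[i2] <- a * s[i2]^3 - 5 * a * s[i2]^2 + 8 * a * s[i2] - 4 * a
  w
}

#' Interpolate a raw stack to isotropic voxel size along the axial direction
#'
#' Light-sheet stacks are sampled coarsely along the detection axis (z step
#' larger than the lateral pixel size). This resamples each (x, y) column
#' along z by cubic-convolution (bicubic) interpolation so that the output
#' voxel is `voxel_xy` on all axes. Lateral planes are untouched; the first
#' slice position is preserved and the number of output slices is
#' `round((nz - 1) * step_z / voxel_xy) + 1`. Interpolation overshoots are
#' clipped at zero.
#'
#' @param data 3D numeric array `(x, y, z)`
#' @param voxel_xy lateral pixel size (micrometers), > 0
#' @param step_z axial step between slices (micrometers), >= `voxel_xy`
#' @return list with `data` (interpolated array) and `voxel` (= `voxel_xy`)
#' @export
interpolate_isotropic <- function(data, voxel_xy, step_z) {
  d <- dim(data)
  if (length(d) != 3L) stop("data must be a 3D array")
  if (voxel_xy <= 0 || step_z <= 0) stop("voxel_xy and step_z must be > 0")
  if (step_z < voxel_xy) stop("step_z must be >= voxel_xy (light-sheet case)")
  nz <- d[3L]
  if (nz < 4L) stop("need at least 4 slices for cubic interpolation")
  if (step_z == voxel_xy) return(list(data = data, voxel = voxel_xy))

  ratio <- step_z / voxel_xy
  n_out <- round((nz - 1) * ratio) + 1L
  # output positions in input slice index units (0-based)
  pos <- pmin((seq_len(n_out) - 1) / ratio, nz - 1)
  out <- array(0, c(d[1L], d[2L], n_out))
  base <- floor(pos)
  frac <- pos - base
  # slice fetch with linear extrapolation for the one virtual slice the
  # 4-tap kernel needs beyond each end (keeps linear ramps exact)
  get_slice <- function(i) {
    if (i >= 1L && i <= nz) data[, , i]
    else if (i == 0L) 2 * data[, , 1L] - data[, , 2L]
    else 2 * data[, , nz] - data[, , nz - 1L]
  }
  for (j in seq_len(n_out)) {
    idx <- base[j] + (-1:2) + 1L
    w <- keys_weight(frac[j] - (-1:2))
    out[, , j] <- w[1] * get_slice(idx[1]) + w[2] * get_slice(idx[2]) +
      w[3] * get_slice(idx[3]) + w[4] * get_slice(idx[4])
  }
  out[out < 0] <- 0
  list(data = out, voxel = voxel_xy)
}

#' Zero-pad an isotropic volume to cubic shape
#'
#' Pads all three extents to the maximum extent with zeros, centering the
#' original data. Returns the padding offsets so results can be cropped
#' back with [crop_by_offsets()].
#'
#' @param data 3D numeric array
#' @return list with `data` (cubic array), `offsets` (integer vector of the
#'   lower padding on each axis) and `original_dim`
#' @export
zero_pad_cubic <- function(data) {
  d <- dim(data)
  if (length(d) != 3L) stop("data must be a 3D array")
  n <- max(d)
  off <- (n - d) %/% 2L
  if (all(d == n))
    return(list(data = data, offsets = c(0L, 0L, 0L), original_dim = d))
  out <- array(0, c(n, n, n))
  out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), off[3] + seq_len(d[3])] <- data
  list(data = out, offsets = off, original_dim = d)
}

#' Crop a padded volume back to its original extents
#'
#' Inverse of [zero_pad_cubic()].
#'
#' @param data padded 3D array
#' @param offsets lower padding offsets as returned by [zero_pad_cubic()]
#' @param original_dim the pre-padding extents
#' @return array of shape `original_dim`
#' @export
crop_by_offsets <- function(data, offsets, original_dim) {
  data[offsets[1] + seq_len(original_dim[1]),
       offsets[2] + seq_len(original_dim[2]),
       offsets[3] + seq_len(original_dim[3]), drop = FALSE]
}
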