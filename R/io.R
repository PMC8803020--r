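## Volume I/O: multi-page TIFF with a JSON sidecar carrying intensity
## scaling and voxel size. Layout convention (documented and asserted in
## tests): TIFF page axis = z, page row axis = y (the rotation axis), page
## column axis = x; in R the volume is an (x, y, z) array.

#' Write a volume as a multi-page TIFF
#'
#' One page per z slice, rows = y, columns = x. TIFF samples are stored as
#' unsigned integers (8/16/32 bit), so intensities are min-max scaled to
#' the full range and the scale and offset are recorded in a JSON sidecar
#' `<path>.json` (together with the voxel size) from which [read_volume()]
#' restores the original values; with 32-bit samples the quantization is
#' below 1e-9 of the intensity range.
#'
#' @param vol 3D numeric array `(x, y, z)` of finite values
#' @param path output TIFF path
#' @param bits bits per sample: 8, 16 or 32 (default)
#' @param voxel voxel edge length (micrometers), recorded in the sidecar
#' @return `path`, invisibly
#' @export
write_volume <- function(vol, path, bits = 32L, voxel = NA_real_) {
  if (length(dim(vol)) != 3L) stop("vol must be a 3D array")
  if (!all(is.finite(vol))) stop("vol contains non-finite values")
  if (!bits %in% c(8L, 16L, 32L)) stop("bits must be 8, 16 or 32")
  lo <- min(vol)
  hi <- max(vol)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(vol)[3L]), function(z)
    t((vol[, , z] - lo) / scale))          # page matrix is (y, x)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  meta <- list(scale = scale, offset = lo, voxel = voxel,
               dim = dim(vol), bits = as.integer(bits),
               layout = "page=z,row=y,col=x")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF volume
#'
#' Counterpart of [write_volume()]: pages become z slices, page rows map
#' to y and columns to x. If a JSON sidecar `<path>.json` is present, the
#' recorded intensity scale/offset are applied and the voxel size is
#' returned; otherwise raw sample values (as read by the TIFF library) are
#' returned with `voxel = NA`.
#'
#' @param path TIFF file path
#' @return list with `data` (3D array `(x, y, z)`) and `voxel`
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- dim(pages[[1L]])
  for (i in seq_along(pages)) {
    if (length(dim(pages[[i]])) != 2L || !identical(dim(pages[[i]]), shp))
      stop("ragged or non-grayscale TIFF page ", i)
  }
  vol <- array(0, c(shp[2L], shp[1L], length(pages)))
  for (z in seq_along(pages)) vol[, , z] <- t(pages[[z]])
  voxel <- NA_real_
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    vol <- vol * meta$scale + meta$offset
    if (!is.null(meta$voxel)) voxel <- meta$voxel
  }
  list(data = vol, voxel = voxel)
}

#' Write a JSON run report
#'
#' Records the configuration, seed, package version, timings and optional
#' per-iteration diagnostics of a run so it can be reproduced exactly.
#'
#' @param path output JSON path
#' @param config a configuration list (e.g. [fusion_config()])
#' @param seed the seed used
#' @param diagnostics optional data frame of per-iteration diagnostics
#' @param timings optional named list of elapsed seconds
#' @return `path`, invisibly
#' @export
write_run_report <- function(path, config, seed = NULL, diagnostics = NULL,
                             timings = NULL) {
  rep <- list(
    package = "mvdeconv",
    version = as.character(utils::packageVersion("mvdeconv")),
    seed = seed,
    config = unclass(config),
    timings = timings,
    diagnostics = diagnostics)
  jsonlite::write_json(rep[!vapply(rep, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}
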