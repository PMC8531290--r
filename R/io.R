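#' Write a hyperspectral object as a 32-bit TIFF stack with a JSON sidecar
#'
#' Interchange format: one 32-bit float TIFF per channel plus an `index.json`
#' sidecar recording the object class, array dimensions, energy axis,
#' angles/voxel size and the channel file names.
#'
#' @param x A [spectral_volume()] or [spectral_sinogram()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix for the channel TIFFs.
#' @return The sidecar path, invisibly.
#' @export
write_tiff_stack <- function(x, dir, prefix = "channel") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  is_vol <- inherits(x, "spectral_volume")
  if (!is_vol && !inherits(x, "spectral_sinogram"))
    stop("x must be a spectral_volume or spectral_sinogram")
  C <- x$axis$n_channels
  files <- sprintf("%s_%04d.tif", prefix, seq_len(C) - 1L)
  # TIFF stores values in [0, 1]; keep the affine scale in the sidecar
  rng <- range(x$data)
  span <- if (diff(rng) > 0) diff(rng) else 1
  for (ch in seq_len(C)) {
    tiff::writeTIFF((x$data[, , ch] - rng[1L]) / span, file.path(dir, files[ch]),
                    bits.per.sample = 32L, reduce = FALSE)
  }
  meta <- list(
    class = if (is_vol) "spectral_volume" else "spectral_sinogram",
    dim = dim(x$data),
    data_min = rng[1L], data_scale = span,
    axis = x$axis[c("n_channels", "offset", "slope", "resolution_fwhm")],
    files = files
  )
  if (is_vol) meta$voxel_size <- x$voxel_size
  else {
    meta$angles <- x$angles
    meta$is_log_normalised <- x$is_log_normalised
  }
  sidecar <- file.path(dir, "index.json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a TIFF stack written by [write_tiff_stack()]
#'
#' @param dir Directory containing the channel TIFFs and `index.json`.
#' @return The reconstructed [spectral_volume()] or [spectral_sinogram()].
#' @export
read_tiff_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "index.json"), simplifyVector = TRUE)
  ax <- energy_axis(meta$axis$n_channels, meta$axis$offset, meta$axis$slope,
                    meta$axis$resolution_fwhm)
  d <- meta$dim
  arr <- array(0, dim = d)
  for (ch in seq_len(d[3L])) {
    img <- tiff::readTIFF(file.path(dir, meta$files[ch]))
    arr[, , ch] <- img * meta$data_scale + meta$data_min
  }
  if (meta$class == "spectral_volume")
    spectral_volume(arr, meta$voxel_size, ax)
  else
    spectral_sinogram(arr, meta$angles, NULL, ax, isTRUE(meta$is_log_normalised))
}

#' Export an ROI spectrum (or any per-channel quantity) as CSV
#'
#' @param values Per-channel numeric vector.
#' @param axis The matching [energy_axis()].
#' @param path Output CSV path; columns `channel` (0-based hardware number),
#'   `kev`, `value`.
#' @param value_name Column name for the values (default `"mean_mu"`).
#' @return The path, invisibly.
#' @export
write_spectrum_csv <- function(values, axis, path, value_name = "mean_mu") {
  stopifnot(length(values) == axis$n_channels)
  df <- data.frame(channel = seq_len(axis$n_channels) - 1L,
                   kev = energies(axis), value = values)
  names(df)[3L] <- value_name
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
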