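#' Hyperspectral sinogram container
#'
#' Holds projection data for every energy channel: a 3D array with dimensions
#' angle x detector-bin x channel.  Before normalisation the values are raw
#' photon counts (non-negative); after flat-field correction and the
#' Beer-Lambert negative-log transform they are line integrals of the linear
#' attenuation coefficient (dimensionless), flagged by `is_log_normalised`.
#'
#' @param data 3D numeric array, angle x detector-bin x channel; all finite.
#' @param angles Numeric vector of projection angles in degrees, one per
#'   array slice along dimension 1.
#' @param geometry An [acquisition_geometry()] (or `NULL` if not yet bound).
#' @param axis An [energy_axis()] with `n_channels == dim(data)[3]`.
#' @param is_log_normalised Logical flag: `TRUE` once the data are
#'   -log(transmission) line integrals.
#' @return An object of class `spectral_sinogram`.
#' @export
spectral_sinogram <- function(data, angles, geometry = NULL, axis,
                              is_log_normalised = FALSE) {
  data <- as_array3(data)
  stopifnot(inherits(axis, "energy_axis"))
  if (dim(data)[1L] != length(angles))
    stop("angle count (", dim(data)[1L], ") != length(angles) (", length(angles), ")")
  if (dim(data)[3L] != axis$n_channels)
    stop("channel count (", dim(data)[3L], ") != axis$n_channels (", axis$n_channels, ")")
  if (!all(is.finite(data))) stop("sinogram values must all be finite")
  if (!is_log_normalised && any(data < 0))
    stop("raw (non-log-normalised) sinogram values must be >= 0")
  structure(
    list(data = data, angles = as.numeric(angles), geometry = geometry,
         axis = axis, is_log_normalised = isTRUE(is_log_normalised)),
    class = "spectral_sinogram"
  )
}

#' @export
print.spectral_sinogram <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_sinogram> %d angles x %d bins x %d channels (%s)\n",
              d[1L], d[2L], d[3L],
              if (x$is_log_normalised) "log-normalised" else "raw"))
  print(x$axis)
  invisible(x)
}

#' Reconstructed hyperspectral volume (single slice)
#'
#' A per-slice reconstruction: a 3D array x-row x y-col x channel of linear
#' attenuation coefficients (mm^-1), with the voxel size and the energy axis.
#'
#' @param data 3D numeric array, row x col x channel; all finite.
#' @param voxel_size Voxel edge length, mm.
#' @param axis An [energy_axis()] with `n_channels == dim(data)[3]`.
#' @return An object of class `spectral_volume`.
#' @export
spectral_volume <- function(data, voxel_size, axis) {
  data <- as_array3(data)
  stopifnot(inherits(axis, "energy_axis"), voxel_size > 0)
  if (dim(data)[3L] != axis$n_channels)
    stop("channel count (", dim(data)[3L], ") != axis$n_channels (", axis$n_channels, ")")
  if (dim(data)[1L] < 1L || dim(data)[2L] < 1L) stop("spatial dims must be >= 1")
  if (!all(is.finite(data))) stop("volume values must all be finite")
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size), axis = axis),
    class = "spectral_volume"
  )
}

#' @export
print.spectral_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_volume> %d x %d voxels (%.4g mm) x %d channels\n",
              d[1L], d[2L], x$voxel_size, d[3L]))
  print(x$axis)
  invisible(x)
}

# coerce matrix (single channel) or 3D array input
as_array3 <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("expected a 3D array (or a matrix for a single channel)")
  storage.mode(x) <- "double"
  x
}

#' Rectangular region of interest
#'
#' ROIs address voxels on the reconstruction grid by their upper-left corner
#' `(row, col)` (1-based, row increasing downward) and extent `(rows, cols)`.
#'
#' @param row,col 1-based indices of the ROI's upper-left voxel.
#' @param rows,cols ROI extent; area must be >= 1.
#' @return An object of class `roi`.
#' @examples
#' roi(10, 10, 5, 5)  # the 5x5 ROIs used for CNR
#' @export
roi <- function(row, col, rows, cols) {
  row <- as.integer(row); col <- as.integer(col)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (row < 1L || col < 1L || rows < 1L || cols < 1L)
    stop("roi indices must be >= 1 and extents >= 1")
  structure(list(row = row, col = col, rows = rows, cols = cols), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> rows %d:%d, cols %d:%d (%d voxels)\n",
              x$row, x$row + x$rows - 1L, x$col, x$col + x$cols - 1L,
              x$rows * x$cols))
  invisible(x)
}

roi_check <- function(r, dims) {
  stopifnot(inherits(r, "roi"))
  if (r$row + r$rows - 1L > dims[1L] || r$col + r$cols - 1L > dims[2L])
    stop("roi extends outside the image grid (", dims[1L], " x ", dims[2L], ")")
  invisible(r)
}

roi_rows <- function(r) seq.int(r$row, r$row + r$rows - 1L)
roi_cols <- function(r) seq.int(r$col, r$col + r$cols - 1L)

#' Restrict a hyperspectral object to a contiguous channel range
#'
#' Keeps array elements `lo:hi` (1-based, inclusive) along the channel
#' dimension and shifts the energy-axis offset so that the retained channels
#' map to exactly the same energies as before.
#'
#' @param x A [spectral_sinogram()] or [spectral_volume()].
#' @param lo,hi First and last channel element to keep, 1-based inclusive,
#'   `1 <= lo <= hi <= n_channels`; at least 2 channels must remain.
#' @return An object of the same class with `hi - lo + 1` channels.
#' @examples
#' # keep hardware channels 100..199 of a 200-channel object: lo = 101, hi = 200
#' @export
select_channel_range <- function(x, lo, hi) UseMethod("select_channel_range")

subset_axis <- function(axis, lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (lo < 1L || hi > axis$n_channels || lo > hi)
    stop("invalid channel range [", lo, ", ", hi, "] for ", axis$n_channels, " channels")
  if (hi - lo + 1L < 2L) stop("at least 2 channels must be retained")
  energy_axis(hi - lo + 1L, offset = axis$offset + axis$slope * (lo - 1L),
              slope = axis$slope, resolution_fwhm = axis$resolution_fwhm)
}

#' @export
select_channel_range.spectral_sinogram <- function(x, lo, hi) {
  ax <- subset_axis(x$axis, lo, hi)
  spectral_sinogram(x$data[, , lo:hi, drop = FALSE], x$angles, x$geometry, ax,
                    x$is_log_normalised)
}

#' @export
select_channel_range.spectral_volume <- function(x, lo, hi) {
  ax <- subset_axis(x$axis, lo, hi)
  spectral_volume(x$data[, , lo:hi, drop = FALSE], x$voxel_size, ax)
}

#' Mean attenuation spectrum of a region of interest
#'
#' Averages the volume over the ROI voxels, channel by channel, giving the
#' mean voxel spectrum of that region (e.g. for inspecting a powder phase's
#' absorption edge).
#'
#' @param v A [spectral_volume()].
#' @param r A [roi()] fully inside the grid.
#' @return Numeric vector of length `n_channels`: per-channel spatial means.
#' @export
extract_roi_spectrum <- function(v, r) {
  stopifnot(inherits(v, "spectral_volume"))
  roi_check(r, dim(v$data))
  sub <- v$data[roi_rows(r), roi_cols(r), , drop = FALSE]
  apply(sub, 3L, mean)
}
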