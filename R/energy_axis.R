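#' Linear channel-to-energy calibration axis
#'
#' Photon-counting hyperspectral detectors bin events into narrow energy
#' channels; the calibration between instrument channel number and photon
#' energy is, to good approximation, linear.  An `energy_axis` stores that
#' linear map together with the detector's energy resolution (FWHM of the
#' spectral response, which broadens any true absorption edge over a few
#' channels).
#'
#' The instrument convention is kept for channel *numbers*: hardware channel
#' `0` has centre energy `offset`, channel `k` has energy `offset + slope * k`.
#' Element `i` of an R array holding channel-resolved data corresponds to
#' hardware channel `i - 1` (R vectors are 1-based).  The channel *width*
#' equals `slope`; channel energies refer to bin centres.
#'
#' @param n_channels Number of energy channels (>= 2).
#' @param offset Energy of hardware channel 0 centre, keV.
#' @param slope Channel width, keV per channel; must be positive.
#' @param resolution_fwhm Detector energy resolution (FWHM), keV.
#' @return An object of class `energy_axis`.
#' @examples
#' ax <- energy_axis(200, offset = 0.68, slope = 0.277)
#' channel_to_energy(ax, c(60, 160))
#' @export
energy_axis <- function(n_channels, offset, slope, resolution_fwhm = 1.2) {
  n_channels <- as.integer(n_channels)
  stopifnot(is.finite(offset), is.finite(slope), is.finite(resolution_fwhm))
  if (n_channels < 2L) stop("energy_axis needs at least 2 channels")
  if (slope <= 0) stop("slope must be > 0 (energy strictly increasing with channel)")
  structure(
    list(n_channels = n_channels, offset = offset, slope = slope,
         resolution_fwhm = resolution_fwhm),
    class = "energy_axis"
  )
}

#' @export
print.energy_axis <- function(x, ...) {
  e <- energies(x)
  cat(sprintf("<energy_axis> %d channels, %.4g keV/channel, %.4g-%.4g keV (FWHM %.3g keV)\n",
              x$n_channels, x$slope, e[1L], e[x$n_channels], x$resolution_fwhm))
  invisible(x)
}

#' Centre energies of all channels of an axis
#'
#' @param axis An [energy_axis()], or any object carrying one in its `axis`
#'   field (a spectral sinogram or volume).
#' @return Numeric vector of length `n_channels`: the centre energy (keV) of
#'   array elements `1..n_channels` (hardware channels `0..n_channels-1`).
#' @export
energies <- function(axis) {
  if (!inherits(axis, "energy_axis") && !is.null(axis$axis)) axis <- axis$axis
  stopifnot(inherits(axis, "energy_axis"))
  axis$offset + axis$slope * (seq_len(axis$n_channels) - 1)
}

#' Convert hardware channel numbers to energies
#'
#' @param axis An [energy_axis()].
#' @param channel Hardware channel number(s), 0-based as labelled by the
#'   instrument; must lie in `[0, n_channels - 1]`.
#' @return Energy value(s) in keV: `offset + slope * channel`.
#' @seealso [energy_to_channel()] for the rounding inverse.
#' @export
channel_to_energy <- function(axis, channel) {
  stopifnot(inherits(axis, "energy_axis"))
  if (any(channel < 0 | channel > axis$n_channels - 1L))
    stop("channel out of range [0, ", axis$n_channels - 1L, "]")
  axis$offset + axis$slope * channel
}

#' Convert energies to nearest hardware channel numbers
#'
#' @param axis An [energy_axis()].
#' @param energy Energy value(s), keV.
#' @return Integer hardware channel number(s) (0-based), rounded to the
#'   nearest channel centre and clamped to the valid range.
#' @export
energy_to_channel <- function(axis, energy) {
  stopifnot(inherits(axis, "energy_axis"))
  ch <- as.integer(round((energy - axis$offset) / axis$slope))
  pmin(pmax(ch, 0L), axis$n_channels - 1L)
}

#' Tabulated K-edge energies of common contrast elements
#'
#' K-shell absorption-edge energies used for chemical fingerprinting in
#' hyperspectral CT.  Values in keV.
#'
#' @return A data.frame with columns `element` and `energy_kev`.
#' @examples
#' kedge_table()
#' @export
kedge_table <- function() {
  data.frame(
    element = c("I", "Ba", "Ce", "Gd", "Yb", "W", "Au", "Pb"),
    energy_kev = c(33.169, 37.441, 40.443, 50.239, 61.332, 69.525, 80.725, 88.005),
    stringsAsFactors = FALSE
  )
}

#' Identify an element from a measured K-edge energy
#'
#' Matches a measured edge energy against [kedge_table()]; a match requires
#' agreement within `tol` (default: one channel width of the supplied axis).
#'
#' @param energy Measured edge energy, keV.
#' @param axis Optional [energy_axis()] supplying the default tolerance.
#' @param tol Match tolerance in keV; defaults to one channel width.
#' @return The matched element symbol, or `NA_character_` if nothing matches.
#' @export
kedge_lookup <- function(energy, axis = NULL, tol = NULL) {
  if (is.null(tol)) {
    tol <- if (!is.null(axis)) axis$slope else 0.5
  }
  tab <- kedge_table()
  d <- abs(tab$energy_kev - energy)
  i <- which.min(d)
  if (d[i] <= tol) tab$element[i] else NA_character_
}
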