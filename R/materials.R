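#' Parametric material attenuation spectrum
#'
#' Linear attenuation over the hard X-ray imaging range is modelled as a
#' smooth power-law decay plus, for elements whose K-shell binding energy
#' falls in range, a broadened step at the K-edge:
#'
#'   mu(E) = a * E^(-p) + c + jump * sigmoid((E - edge_energy) / edge_width)
#'
#' The power law captures the photoelectric fall-off with energy; the
#' logistic step captures the K-edge discontinuity as seen through a detector
#' of finite energy resolution (`edge_width` plays the role of the detector
#' broadening, so the "discontinuity" spans a few channels, exactly as a
#' photon-counting detector records it).
#'
#' @param name Label for the material.
#' @param a,p Power-law amplitude (keV^p mm^-1) and exponent (dimensionless).
#' @param c Constant baseline, mm^-1 (Compton floor).
#' @param edge_energy K-edge energy in keV, or `NA` for edgeless materials.
#' @param edge_jump Attenuation step at the edge, mm^-1; must be >= 0.
#' @param edge_width Sigmoid broadening scale, keV; > 0 when an edge is present.
#' @return An object of class `material_spectrum`.
#' @examples
#' ceo2 <- material_presets()$ceria
#' material_attenuation(ceo2, c(35, 40, 45))
#' @export
material_spectrum <- function(name, a, p, c = 0, edge_energy = NA_real_,
                              edge_jump = 0, edge_width = 0.4) {
  if (edge_jump < 0) stop("edge_jump must be >= 0")
  if (!is.na(edge_energy) && edge_width <= 0)
    stop("edge_width must be > 0 when an edge is present")
  structure(
    list(name = name, a = a, p = p, c = c, edge_energy = edge_energy,
         edge_jump = edge_jump, edge_width = edge_width),
    class = "material_spectrum"
  )
}

#' @export
print.material_spectrum <- function(x, ...) {
  edge <- if (is.na(x$edge_energy)) "no K-edge" else
    sprintf("K-edge %.3f keV (jump %.3g mm^-1, width %.2g keV)", x$edge_energy,
            x$edge_jump, x$edge_width)
  cat(sprintf("<material_spectrum> %s: mu(E) = %.3g E^-%.3g + %.3g, %s\n",
              x$name, x$a, x$p, x$c, edge))
  invisible(x)
}

#' Evaluate a material's attenuation at given energies
#'
#' @param m A [material_spectrum()].
#' @param energies Energies in keV (positive).
#' @return Numeric vector of linear attenuation coefficients, mm^-1,
#'   strictly positive (non-physical parameter sets are rejected).
#' @export
material_attenuation <- function(m, energies) {
  stopifnot(inherits(m, "material_spectrum"))
  if (any(energies <= 0)) stop("energies must be positive")
  mu <- m$a * energies^(-m$p) + m$c
  if (!is.na(m$edge_energy) && m$edge_jump > 0) {
    mu <- mu + m$edge_jump * stats::plogis((energies - m$edge_energy) / m$edge_width)
  }
  if (any(mu <= 0))
    stop("non-physical material '", m$name, "': mu(E) <= 0 within requested range")
  mu
}

#' Built-in material presets for the K-edge phantom simulator
#'
#' Package defaults emulating the attenuation scale (mm^-1, 15-60 keV) of the
#' materials used in hyperspectral K-edge imaging studies: a lightly
#' attenuating aluminium-like matrix, a cerium-oxide-like powder whose K-edge
#' (40.443 keV) is in range, edgeless zinc-oxide- and iron-like powders,
#' iodine-stained soft tissue (I K-edge 33.169 keV), water/agarose background
#' and a hydroxyapatite-like bone mineral.  Parameter values are package
#' defaults on a realistic scale, not measured constants.
#'
#' @return Named list of [material_spectrum()] objects.
#' @export
material_presets <- function() {
  list(
    aluminium = material_spectrum("Al-like matrix", a = 300, p = 2, c = 0.02),
    ceria = material_spectrum("CeO2-like powder", a = 1800, p = 2, c = 0.05,
                              edge_energy = 40.443, edge_jump = 1.0,
                              edge_width = 0.4),
    zinc_oxide = material_spectrum("ZnO-like powder", a = 900, p = 2, c = 0.03),
    iron = material_spectrum("Fe-like powder", a = 1300, p = 2, c = 0.04),
    iodine_tissue = material_spectrum("iodine-stained tissue", a = 120, p = 2,
                                      c = 0.03, edge_energy = 33.169,
                                      edge_jump = 0.35, edge_width = 0.4),
    water = material_spectrum("water/agarose", a = 60, p = 2, c = 0.02),
    bone = material_spectrum("HA-like bone", a = 450, p = 2, c = 0.03)
  )
}

#' Load a tabulated attenuation spectrum from CSV
#'
#' Extension point for users with tabulated mu(E) data: reads a two-column
#' CSV (`energy_kev`, `mu_mm`) and returns an interpolating function.
#'
#' @param path CSV file with columns `energy_kev` and `mu_mm`.
#' @return A function `f(energies)` linearly interpolating the table.
#' @export
material_table_csv <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("energy_kev", "mu_mm") %in% names(tab)))
    stop("CSV must have columns 'energy_kev' and 'mu_mm'")
  stats::approxfun(tab$energy_kev, tab$mu_mm, rule = 2)
}
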