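#' Multi-material phantom layout
#'
#' Describes a cylindrical (disk, per slice) matrix with circular inserts,
#' mimicking test phantoms drilled with powder-filled holes.  Each insert
#' carries a material and a concentration fraction `f` in `[0, 1]`; the voxel
#' spectrum inside an insert is the linear mixture
#' `(1 - f) * mu_matrix(E) + f * mu_insert(E)`.
#'
#' @param n Grid size (n x n voxels).
#' @param voxel_size Voxel edge, mm.
#' @param matrix_material [material_spectrum()] of the matrix disk.
#' @param inserts List of inserts, each a list with fields `cx`, `cy` (centre,
#'   voxel units, 1-based grid coordinates), `radius` (voxels), `material`
#'   (a [material_spectrum()]) and `concentration` in `[0, 1]` (default 1).
#' @param matrix_radius Radius of the matrix disk in voxels (default `n/2 - 1`).
#' @param background_material Optional [material_spectrum()] outside the
#'   matrix disk (default: vacuum, mu = 0).
#' @return An object of class `phantom_layout`.
#' @export
phantom_layout <- function(n, voxel_size, matrix_material, inserts = list(),
                           matrix_radius = n / 2 - 1,
                           background_material = NULL) {
  stopifnot(n >= 4, voxel_size > 0, inherits(matrix_material, "material_spectrum"))
  for (ins in inserts) {
    stopifnot(inherits(ins$material, "material_spectrum"))
    f <- if (is.null(ins$concentration)) 1 else ins$concentration
    if (f < 0 || f > 1) stop("insert concentration must be in [0, 1]")
    d <- sqrt((ins$cx - (n + 1) / 2)^2 + (ins$cy - (n + 1) / 2)^2)
    if (d + ins$radius > matrix_radius)
      stop("insert '", ins$material$name, "' extends outside the matrix disk")
  }
  # reject overlapping inserts
  if (length(inserts) > 1L) {
    for (i in seq_along(inserts)) for (j in seq_len(i - 1L)) {
      a <- inserts[[i]]; b <- inserts[[j]]
      if (sqrt((a$cx - b$cx)^2 + (a$cy - b$cy)^2) < a$radius + b$radius)
        stop("inserts ", j, " and ", i, " overlap")
    }
  }
  structure(
    list(n = as.integer(n), voxel_size = voxel_size,
         matrix_material = matrix_material, inserts = inserts,
         matrix_radius = matrix_radius, background_material = background_material),
    class = "phantom_layout"
  )
}

#' Rasterise a phantom layout into a ground-truth spectral volume
#'
#' Evaluates every material at the axis' channel-centre energies and fills a
#' row x col x channel volume; insert voxels get the linear concentration
#' mixture of matrix and insert spectra.  Also returns a label map recording
#' membership (0 = background, 1 = matrix, 2, 3, ... = inserts in order).
#'
#' @param layout A [phantom_layout()].
#' @param axis An [energy_axis()].
#' @return List with `volume` (a [spectral_volume()]) and `labels`
#'   (integer matrix n x n).
#' @export
build_phantom <- function(layout, axis) {
  stopifnot(inherits(layout, "phantom_layout"), inherits(axis, "energy_axis"))
  n <- layout$n
  e <- energies(axis)
  C <- axis$n_channels
  mu_matrix <- material_attenuation(layout$matrix_material, e)
  mu_bg <- if (is.null(layout$background_material)) rep(0, C) else
    material_attenuation(layout$background_material, e)

  cx0 <- (n + 1) / 2
  rowi <- matrix(seq_len(n), n, n)           # row index (y, downward)
  coli <- matrix(seq_len(n), n, n, byrow = TRUE)
  rr <- sqrt((rowi - cx0)^2 + (coli - cx0)^2)
  in_matrix <- rr <= layout$matrix_radius

  vol <- array(0, dim = c(n, n, C))
  labels <- matrix(0L, n, n)
  labels[in_matrix] <- 1L
  for (ch in seq_len(C)) {
    slab <- matrix(mu_bg[ch], n, n)
    slab[in_matrix] <- mu_matrix[ch]
    vol[, , ch] <- slab
  }
  for (k in seq_along(layout$inserts)) {
    ins <- layout$inserts[[k]]
    f <- if (is.null(ins$concentration)) 1 else ins$concentration
    mu_ins <- material_attenuation(ins$material, e)
    mix <- (1 - f) * mu_matrix + f * mu_ins
    inside <- sqrt((rowi - ins$cy)^2 + (coli - ins$cx)^2) <= ins$radius
    labels[inside] <- k + 1L
    idx <- which(inside)
    for (ch in seq_len(C)) {
      slab <- vol[, , ch]
      slab[idx] <- mix[ch]
      vol[, , ch] <- slab
    }
  }
  list(volume = spectral_volume(vol, layout$voxel_size, axis), labels = labels)
}
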