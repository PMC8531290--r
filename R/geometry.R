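#' 2D parallel-beam acquisition geometry
#'
#' Per-slice parallel-beam geometry: the cone-beam analytic pipeline of real
#' scanners is represented at desk scale by its central-slice 2D parallel
#' equivalent, which preserves every analytic-vs-regularised comparison this
#' package makes.  Angle 0 degrees projects along +y; angles are given in
#' degrees and converted to radians internally.
#'
#' @param n Image grid size (n x n voxels).
#' @param voxel_size Voxel edge, mm.
#' @param angles Projection angles in degrees, each in `[0, 360)`.
#' @param n_detector_bins Number of detector bins; the detector must span the
#'   image diagonal (default chooses `ceiling(n * sqrt(2)) + 3`).
#' @param detector_pixel_mm Detector bin width, mm (default: `voxel_size`).
#' @return An object of class `acquisition_geometry`.  The sparse system
#'   matrix is built lazily on first use and cached inside the object's
#'   environment.
#' @export
acquisition_geometry <- function(n, voxel_size, angles,
                                 n_detector_bins = ceiling(n * sqrt(2)) + 3,
                                 detector_pixel_mm = voxel_size) {
  stopifnot(n >= 2, voxel_size > 0, length(angles) >= 1, detector_pixel_mm > 0)
  if (any(angles < 0 | angles >= 360)) stop("angles must lie in [0, 360)")
  if (n_detector_bins * detector_pixel_mm < n * voxel_size * sqrt(2))
    stop("detector does not span the image diagonal")
  g <- new.env(parent = emptyenv())
  g$n <- as.integer(n)
  g$voxel_size <- voxel_size
  g$angles <- as.numeric(angles)
  g$n_detector_bins <- as.integer(n_detector_bins)
  g$detector_pixel_mm <- detector_pixel_mm
  g$A <- NULL  # sparse system matrix cache
  class(g) <- "acquisition_geometry"
  g
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf("<acquisition_geometry> parallel-2D: %d x %d grid (%.4g mm), %d angles, %d bins (%.4g mm)\n",
              x$n, x$n, x$voxel_size, length(x$angles), x$n_detector_bins,
              x$detector_pixel_mm))
  invisible(x)
}

# Sparse system matrix by Joseph's method: each ray is sampled at steps of
# one voxel length; samples take bilinear interpolation weights from the 4
# surrounding voxels, scaled by the step length, so A u gives line integrals
# in mm^-1 * mm (dimensionless).  Rows are ordered angle-fastest to match
# as.vector(sino[angle, bin]) for a single channel.
system_matrix <- function(g) {
  if (!is.null(g$A)) return(g$A)
  n <- g$n; v <- g$voxel_size
  nb <- g$n_detector_bins; pd <- g$detector_pixel_mm
  na <- length(g$angles)
  th <- g$angles * pi / 180
  c0 <- (n + 1) / 2
  s <- (seq_len(nb) - (nb + 1) / 2) * pd      # detector coordinates, mm
  half_diag <- n * v * sqrt(2) / 2
  tt <- seq(-half_diag, half_diag, by = v)    # sample positions along ray, mm
  nt <- length(tt)

  ii <- vector("list", na); jj <- vector("list", na); xx <- vector("list", na)
  for (a in seq_len(na)) {
    es <- c(cos(th[a]), sin(th[a]))           # detector axis
    er <- c(-sin(th[a]), cos(th[a]))          # ray direction (angle 0 -> +y)
    # sample points for all (bin, t) pairs
    px <- outer(s * es[1], tt * er[1], `+`)   # nb x nt
    py <- outer(s * es[2], tt * er[2], `+`)
    fj <- px / v + c0                         # fractional col index (x)
    fi <- c0 - py / v                         # fractional row index (y, downward)
    j0 <- floor(fj); i0 <- floor(fi)
    wj <- fj - j0;  wi <- fi - i0
    row_of <- matrix(rep(a + (seq_len(nb) - 1L) * na, nt), nb, nt)
    acc_i <- integer(0); acc_j <- integer(0); acc_x <- numeric(0)
    for (q in 1:4) {
      di <- (q - 1L) %% 2L; dj <- (q - 1L) %/% 2L
      pi_ <- i0 + di; pj_ <- j0 + dj
      w <- (if (di == 1L) wi else 1 - wi) * (if (dj == 1L) wj else 1 - wj)
      ok <- pi_ >= 1 & pi_ <= n & pj_ >= 1 & pj_ <= n & w > 0
      if (any(ok)) {
        acc_i <- c(acc_i, row_of[ok])
        acc_j <- c(acc_j, (pi_[ok] + (pj_[ok] - 1L) * n))
        acc_x <- c(acc_x, w[ok] * v)
      }
    }
    ii[[a]] <- acc_i; jj[[a]] <- acc_j; xx[[a]] <- acc_x
  }
  g$A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                              dims = c(na * nb, n * n))
  g$A
}

#' Forward-project an image (line integrals)
#'
#' Applies the linear parallel-beam projector (Joseph kernel, step length one
#' voxel, bilinear interpolation) to one or more channels.
#'
#' @param u Single-channel image (n x n matrix) or an `n x n x C` array.
#' @param g An [acquisition_geometry()].
#' @return Sinogram: `n_angles x n_bins` matrix (or `x C` array).
#' @export
forward_project <- function(u, g) {
  stopifnot(inherits(g, "acquisition_geometry"))
  A <- system_matrix(g)
  na <- length(g$angles); nb <- g$n_detector_bins
  single <- is.matrix(u)
  u3 <- as_array3(u)
  if (dim(u3)[1L] != g$n || dim(u3)[2L] != g$n)
    stop("image shape ", dim(u3)[1L], "x", dim(u3)[2L],
         " does not match grid ", g$n, "x", g$n)
  C <- dim(u3)[3L]
  um <- matrix(u3, g$n * g$n, C)
  sm <- as.matrix(A %*% um)
  out <- array(sm, dim = c(na, nb, C))
  if (single) matrix(out[, , 1L], na, nb) else out
}

#' Back-project a sinogram (exact adjoint of the forward projector)
#'
#' Applies the transpose of the sparse system matrix, so
#' `sum(forward_project(x, g) * y) == sum(x * back_project(y, g))` holds to
#' machine precision — the property the saddle-point solver depends on.
#'
#' @param s Single-channel sinogram (`n_angles x n_bins` matrix) or
#'   `n_angles x n_bins x C` array.
#' @param g An [acquisition_geometry()].
#' @return Image: n x n matrix (or `x C` array).
#' @export
back_project <- function(s, g) {
  stopifnot(inherits(g, "acquisition_geometry"))
  A <- system_matrix(g)
  na <- length(g$angles); nb <- g$n_detector_bins
  single <- is.matrix(s)
  s3 <- as_array3(s)
  if (dim(s3)[1L] != na || dim(s3)[2L] != nb)
    stop("sinogram shape ", dim(s3)[1L], "x", dim(s3)[2L],
         " does not match geometry ", na, "x", nb)
  C <- dim(s3)[3L]
  sm <- matrix(s3, na * nb, C)
  um <- as.matrix(Matrix::crossprod(A, sm))
  out <- array(um, dim = c(g$n, g$n, C))
  if (single) matrix(out[, , 1L], g$n, g$n) else out
}

#' Power-iteration estimate of a linear operator's norm
#'
#' Estimates the largest singular value of a linear operator given as a
#' forward/adjoint function pair, by power iteration on the normal operator.
#' Used to set stable primal-dual step sizes.
#'
#' @param forward Function mapping an input array to the operator's output.
#' @param adjoint Function mapping an output array back to input space.
#' @param dim_in Dimensions of the operator's input.
#' @param n_iter Number of power iterations (>= 1); the estimate is
#'   nondecreasing in `n_iter` up to convergence.
#' @param seed Seed for the random start vector (local RNG stream).
#' @return Scalar estimate of the operator 2-norm.
#' @examples
#' operator_norm(identity, identity, dim_in = 16)  # 1
#' @export
operator_norm <- function(forward, adjoint, dim_in, n_iter = 20, seed = 17L) {
  stopifnot(n_iter >= 1)
  x <- with_local_seed(seed, array(stats::rnorm(prod(dim_in)), dim = dim_in))
  x <- x / sqrt(sum(x^2))
  nrm <- 0
  for (k in seq_len(n_iter)) {
    y <- adjoint(forward(x))
    nrm <- sqrt(sum(y * x))          # Rayleigh quotient of A^T A, ||x|| = 1
    ny <- sqrt(sum(y^2))
    if (ny == 0) return(0)
    x <- y / ny
  }
  nrm
}

#' Norm of the stacked reconstruction operator
#'
#' Power-iteration estimate of the norm of the stacked operator
#' `K(u, w) = (A u, grad_xy u, D_c u - w, D_c w)` used by the TV-TGV solver.
#'
#' @param g An [acquisition_geometry()].
#' @param n_channels Number of energy channels of the problem.
#' @param n_iter Power iterations (default 20).
#' @return Scalar norm estimate.
#' @export
recon_operator_norm <- function(g, n_channels, n_iter = 20) {
  op <- list(fwd = function(u) forward_project(u, g),
             adj = function(y) back_project(y, g))
  stacked_operator_norm(op, c(g$n, g$n, n_channels), n_iter = n_iter)
}

# norm of K(u, w) = (A u, grad_xy u, D_c u - w, D_c w) for a generic data
# operator A given as an fwd/adj pair on row x col x channel arrays
stacked_operator_norm <- function(op, dims, n_iter = 20) {
  nu <- prod(dims)
  fwd <- function(x) {
    u <- array(x[seq_len(nu)], dim = dims)
    w <- array(x[-seq_len(nu)], dim = dims)
    c(op$fwd(u), dx_fwd(u), dy_fwd(u), dc_fwd(u) - mask_lastc(w), dc2_fwd(w))
  }
  data_dim <- dim(op$fwd(array(0, dim = dims)))
  n_data <- prod(data_dim)
  adj <- function(y) {
    au <- array(y[seq_len(n_data)], dim = data_dim)
    ofs <- n_data
    gx <- array(y[ofs + seq_len(nu)], dim = dims); ofs <- ofs + nu
    gy <- array(y[ofs + seq_len(nu)], dim = dims); ofs <- ofs + nu
    y3 <- array(y[ofs + seq_len(nu)], dim = dims); ofs <- ofs + nu
    y4 <- array(y[ofs + seq_len(nu)], dim = dims)
    ut <- op$adj(au) + dx_adj(gx) + dy_adj(gy) + dc_adj(y3)
    wt <- -mask_lastc(y3) + dc2_adj(y4)
    c(ut, wt)
  }
  operator_norm(fwd, adj, dim_in = 2 * nu, n_iter = n_iter)
}

# evaluate expr under a temporary RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
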