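# Shared deterministic scenes and independent oracles.  Everything heavy is
# memoised so the whole suite pays for each simulation / reconstruction once.

.scene_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, .scene_cache, inherits = FALSE))
    assign(key, builder(), envir = .scene_cache)
  get(key, .scene_cache, inherits = FALSE)
}

scenes <- function() memo("fixtures", function() make_fixtures(1))

# Scan-B-analogue benchmark: 32-channel subset, preprocessing, channel-wise
# FBP and the 1000-iteration TV-TGV solve (the expensive shared object).
bench_scanB <- function() memo("bench_scanB", function() {
  fx <- scenes()
  sb <- fx$cerium$scan_b
  raw <- select_channel_range(sb$scan$raw, 13, 44)
  truth <- select_channel_range(fx$cerium$truth, 13, 44)
  b <- negative_log(flat_field_correct(raw, sb$scan$flats[, , 13:44]))
  fbp <- fbp_reconstruct(b, sb$geometry)
  prob <- recon_problem(b, sb$geometry, alpha = 0.002, beta1 = 0.18,
                        beta2 = 0.25, n_iter = 1000)
  tvtgv <- pdhg_solve(prob, trace_every = 10)
  list(b = b, geometry = sb$geometry, truth = truth, fbp = fbp, tvtgv = tvtgv,
       roi_signal = roi(21, 39, 5, 5),     # ceria insert (cx 41, cy 23)
       roi_background = roi(30, 28, 5, 5)) # aluminium matrix
})

scanA_fbp <- function() memo("scanA_fbp", function() {
  fx <- scenes()
  sa <- fx$cerium$scan_a
  b <- negative_log(flat_field_correct(sa$scan$raw, sa$scan$flats))
  fbp_reconstruct(b, sa$geometry)
})

iodine_fbp <- function() memo("iodine_fbp", function() {
  fx <- scenes()
  io <- fx$iodine$scan
  b <- negative_log(flat_field_correct(io$scan$raw, io$scan$flats))
  fbp_reconstruct(b, io$geometry)
})

# small dense geometry used by several solver tests
tiny_problem <- function(n = 16, C = 4, n_angles = 32, seed = 7) {
  ang <- seq(0, 360, length.out = n_angles + 1L)[seq_len(n_angles)]
  g <- acquisition_geometry(n, 0.2, ang)
  utrue <- with_seed(seed, array(runif(n * n * C), c(n, n, C)))
  b <- forward_project(utrue, g)
  axis <- energy_axis(C, 30, 1)
  list(g = g, utrue = utrue,
       b = spectral_sinogram(b, ang, g, axis, is_log_normalised = TRUE),
       axis = axis)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# interior forward-difference matrix mapping R^n -> R^(n-1), the discrete
# operator the spectral TGV terms are built on (slope field on the staggered
# difference grid)
interior_diff_matrix <- function(n) {
  D <- matrix(0, n - 1L, n)
  for (i in seq_len(n - 1L)) { D[i, i] <- -1; D[i, i + 1L] <- 1 }
  D
}

# Independent ADMM oracle for 1D TGV denoising on the staggered grid:
#   min_{u in R^C, w in R^(C-1)} ||u - y||^2 + b1 ||D1 u - w||_1 + b2 ||D2 w||_1
# Different splitting and algorithm from the package's PDHG path; the
# (u, w) block is an exact linear solve, the l1 blocks are soft-thresholds.
admm_tgv_denoise <- function(y, b1, b2, rho = 1, iters = 5000) {
  C <- length(y)
  D1 <- interior_diff_matrix(C)              # (C-1) x C
  D2 <- interior_diff_matrix(C - 1L)         # (C-2) x (C-1)
  z1 <- l1 <- rep(0, C - 1L); z2 <- l2 <- rep(0, C - 2L)
  Amat <- rbind(
    cbind(2 * diag(C) + rho * crossprod(D1), -rho * t(D1)),
    cbind(-rho * D1, rho * diag(C - 1L) + rho * crossprod(D2)))
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  u <- y; w <- rep(0, C - 1L)
  for (k in seq_len(iters)) {
    rhs <- c(2 * y + rho * crossprod(D1, z1 - l1),
             -rho * (z1 - l1) + rho * crossprod(D2, z2 - l2))
    uw <- solve(Amat, rhs)
    u <- uw[seq_len(C)]; w <- uw[C + seq_len(C - 1L)]
    z1 <- as.vector(soft(D1 %*% u - w + l1, b1 / rho))
    z2 <- as.vector(soft(D2 %*% w + l2, b2 / rho))
    l1 <- as.vector(l1 + D1 %*% u - w - z1)
    l2 <- as.vector(l2 + D2 %*% w - z2)
  }
  list(u = u, w = w,
       objective = sum((u - y)^2) + b1 * sum(abs(D1 %*% u - w)) +
         b2 * sum(abs(D2 %*% w)))
}
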