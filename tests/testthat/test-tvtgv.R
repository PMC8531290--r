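test_that("spatial TV has the expected values and norm properties", {
  expect_identical(tv_spatial(matrix(0.7, 5, 5)), 0)
  # hand evaluation with forward differences and Neumann boundary
  expect_equal(tv_spatial(matrix(c(0, 0, 1, 1), 2, 2)), 2)
  u <- with_seed(4, array(rnorm(6 * 6 * 3), c(6, 6, 3)))
  expect_equal(tv_spatial(2 * u), 2 * tv_spatial(u))
  expect_gte(tv_spatial(u), 0)
})

test_that("spectral TGV vanishes on affine spectra and measures kinks", {
  C <- 8
  ch <- seq_len(C)
  aff <- array(2 + 0.5 * ch, c(1, 1, C))     # affine in channel
  w_slope <- array(c(rep(0.5, C - 1), 0), c(1, 1, C))
  expect_identical(tgv_spectral(aff, w_slope, 1, 1), 0)
  # w = D_c u makes the first term vanish exactly
  u <- array(with_seed(5, rnorm(C)), c(1, 1, C))
  Du <- array(c(diff(as.vector(u)), 0), c(1, 1, C))
  D2u <- diff(diff(as.vector(u)))            # C - 2 interior second differences
  expect_equal(tgv_spectral(u, Du, 3, 2), 2 * sum(abs(D2u)))
})

test_that("one kink costs beta2 times the slope change at the optimal w", {
  # piecewise-affine spectrum: slope 0.2 then slope 0.9 (kink at channel 4)
  C <- 8; b1 <- 1; b2 <- 1
  slopes <- c(rep(0.2, 3), rep(0.9, 4))
  u <- array(cumsum(c(1, slopes)), c(1, 1, C))
  Du <- c(diff(as.vector(u)), 0)
  # brute-force minimisation over w restricted to the candidate set where an
  # optimum of this piecewise-linear objective must lie: step functions in
  # the observed slopes (all change points) plus w = D_c u itself
  cands <- list(Du)
  for (k in 0:C) cands[[length(cands) + 1L]] <-
    c(rep(0.2, k), rep(0.9, C - k))
  for (k in 0:C) cands[[length(cands) + 1L]] <-
    c(rep(0.9, k), rep(0.2, C - k))
  vals <- vapply(cands, function(w)
    tgv_spectral(u, array(w, c(1, 1, C)), b1, b2), numeric(1))
  expect_equal(min(vals), b2 * abs(0.9 - 0.2), tolerance = 1e-12)
  # the minimiser is the slope field w = D_c u itself
  expect_equal(tgv_spectral(u, array(Du, c(1, 1, C)), b1, b2), min(vals))
})

test_that("zero data with any regularisation gives the exact zero solution", {
  tp <- tiny_problem(n = 8, C = 2, n_angles = 8)
  zero <- spectral_sinogram(array(0, dim = dim(tp$b$data)), tp$b$angles,
                            tp$g, tp$axis, is_log_normalised = TRUE)
  p <- recon_problem(zero, tp$g, 0.01, 0.01, 0.01, n_iter = 20)
  sol <- pdhg_solve(p)
  expect_identical(max(abs(sol$volume$data)), 0)
})

test_that("zero regularisation reproduces the least-squares solution", {
  tp <- tiny_problem(n = 16, C = 4, n_angles = 32)
  # independent oracle: dense normal-equations solve
  A <- as.matrix(spectralct:::system_matrix(tp$g))
  bm <- matrix(tp$b$data, dim(tp$b$data)[1] * dim(tp$b$data)[2], 4)
  u_ls <- solve(crossprod(A), crossprod(A, bm))
  nk <- recon_operator_norm(tp$g, 4)
  p <- recon_problem(tp$b, tp$g, 0, 0, 0, n_iter = 5000, gap_tol = 0,
                     sigma = 0.99 / (10 * nk), tau = 0.99 * 10 / nk,
                     norm_K = nk)
  sol <- pdhg_solve(p, trace_every = 1000)
  u_hat <- matrix(sol$volume$data, 16 * 16, 4)
  expect_lt(sqrt(sum((u_hat - u_ls)^2) / sum(u_ls^2)), 1e-3)
})

test_that("1D spectral TGV denoising matches an independent ADMM oracle", {
  C <- 8
  yspec <- c(1, 1.1, 1.2, 1.3, 2.3, 2.4, 2.5, 2.6) +
    with_seed(3, rnorm(C, 0, 0.05))
  b1 <- 0.3; b2 <- 0.4
  oracle <- admm_tgv_denoise(yspec, b1, b2, rho = 1, iters = 5000)
  ax <- energy_axis(C, 30, 1)
  v <- spectral_volume(array(yspec, c(1, 1, C)), 0.1, ax)
  p <- denoise_problem(v, alpha = 0, beta1 = b1, beta2 = b2,
                       n_iter = 20000, gap_tol = 1e-12)
  sol <- pdhg_solve(p, trace_every = 5000)
  u <- as.vector(sol$volume$data)
  expect_lt(sqrt(sum((u - oracle$u)^2) / sum(oracle$u^2)), 1e-3)
})

test_that("the primal-dual gap is nonnegative, eventually decreasing, and reaches tolerance", {
  tp <- tiny_problem(n = 12, C = 3, n_angles = 16)
  p <- recon_problem(tp$b, tp$g, 0.01, 0.05, 0.07, n_iter = 4000,
                     gap_tol = 1e-4)
  sol <- pdhg_solve(p)
  tr <- sol$trace
  expect_true(all(tr$gap > -1e-8 * tr$gap[1]))
  expect_true(sol$converged)
  expect_lt(tail(tr$gap, 1) / tr$gap[1], 1e-4)
  # eventually decreasing: monotone over the last quarter of the trace
  lastq <- tail(tr$gap, max(5, nrow(tr) %/% 4))
  expect_true(all(diff(lastq) <= 1e-10 * tr$gap[1]))
})

test_that("with no spectral coupling the solve decouples into per-channel TV", {
  tp <- tiny_problem(n = 12, C = 3, n_angles = 16)
  p_all <- recon_problem(tp$b, tp$g, 0.05, 0, 0, n_iter = 3000, gap_tol = 0)
  sol_all <- pdhg_solve(p_all, trace_every = 1000)
  for (ch in 1:3) {
    ax1 <- energy_axis(2, 30, 1)  # minimal two-channel container
    bch <- array(rep(tp$b$data[, , ch], 2), c(dim(tp$b$data)[1:2], 2))
    b1 <- spectral_sinogram(bch, tp$b$angles, tp$g, ax1, is_log_normalised = TRUE)
    p1 <- recon_problem(b1, tp$g, 0.05, 0, 0, n_iter = 3000, gap_tol = 0)
    sol1 <- pdhg_solve(p1, trace_every = 1000)
    expect_lt(max(abs(sol_all$volume$data[, , ch] - sol1$volume$data[, , 1])) /
                max(abs(sol1$volume$data[, , 1])), 1e-3)
  }
})

test_that("stronger spatial regularisation never increases the solution's TV", {
  tp <- tiny_problem(n = 12, C = 2, n_angles = 12)
  noisy <- tp$b
  noisy$data <- noisy$data + with_seed(21, array(rnorm(length(noisy$data), 0, 0.05),
                                                 dim = dim(noisy$data)))
  tvs <- vapply(c(0.005, 0.05, 0.5), function(a) {
    sol <- pdhg_solve(recon_problem(noisy, tp$g, a, 0.01, 0.014,
                                    n_iter = 1500, gap_tol = 0),
                      trace_every = 500)
    tv_spatial(sol$volume$data)
  }, numeric(1))
  expect_true(all(diff(tvs) <= 1e-6 * tvs[1]))
})

# w = D_c u, the natural slope field of an arbitrary volume
dc_slope_field <- function(u) {
  C <- dim(u)[3]
  d <- u
  d[, , -C] <- u[, , -1, drop = FALSE] - u[, , -C, drop = FALSE]
  d[, , C] <- 0
  d
}

test_that("the regularised solution beats FBP under its own objective on noisy data", {
  bench <- bench_scanB()
  p <- bench$tvtgv$problem
  obj <- function(u, w) {
    sum((forward_project(u, bench$geometry) - bench$b$data)^2) +
      p$alpha * tv_spatial(u) + tgv_spectral(u, w, p$beta1, p$beta2)
  }
  u_fbp <- bench$fbp$data
  w_fbp <- dc_slope_field(u_fbp)             # best simple w for the FBP image
  expect_lt(obj(bench$tvtgv$volume$data, bench$tvtgv$w), obj(u_fbp, w_fbp))
})

test_that("unstable step sizes are rejected before iterating", {
  tp <- tiny_problem(n = 8, C = 2, n_angles = 8)
  nk <- recon_operator_norm(tp$g, 2)
  expect_error(recon_problem(tp$b, tp$g, 0.01, 0.01, 0.01,
                             sigma = 2 / nk, tau = 2 / nk, norm_K = nk),
               "divergence")
  expect_error(recon_problem(tp$b, tp$g, -0.1, 0.01, 0.01), ">= 0")
})
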