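test_that("line integrals match chord lengths through a uniform disk", {
  ax <- energy_axis(2, 30, 1)
  m <- material_spectrum("m", a = 0, p = 1, c = 0.5)
  ph <- build_phantom(phantom_layout(64, 0.1, m, matrix_radius = 20), ax)
  g <- acquisition_geometry(64, 0.1, 0)
  s <- forward_project(ph$volume$data[, , 1], g)
  expect_equal(max(s), 2 * 20 * 0.1 * 0.5, tolerance = 0.01)  # central chord
  expect_identical(forward_project(matrix(0, 64, 64), g),
                   matrix(0, 1, g$n_detector_bins))
})

test_that("a single bright pixel traces a sinusoid across angles", {
  n <- 32
  ang <- seq(0, 360, length.out = 37)[1:36]
  g <- acquisition_geometry(n, 0.1, ang)
  img <- matrix(0, n, n)
  img[10, 22] <- 1
  s <- forward_project(img, g)
  # geometric oracle: the pixel centre projects onto detector coordinate
  # x cos(th) + y sin(th); the argmax bin must follow it at every angle
  c0 <- (n + 1) / 2
  x <- (22 - c0) * 0.1; y <- (c0 - 10) * 0.1
  for (a in seq_along(ang)) {
    th <- ang[a] * pi / 180
    sp <- x * cos(th) + y * sin(th)
    k_pred <- sp / g$detector_pixel_mm + (g$n_detector_bins + 1) / 2
    expect_lt(abs(which.max(s[a, ]) - k_pred), 1.5)
  }
})

test_that("back projection is the exact adjoint and is linear", {
  g <- acquisition_geometry(24, 0.15, seq(0, 360, length.out = 19)[1:18])
  for (trial in 1:5) {
    x <- with_seed(100 + trial, matrix(rnorm(24 * 24), 24, 24))
    y <- with_seed(200 + trial,
                   matrix(rnorm(18 * g$n_detector_bins), 18, g$n_detector_bins))
    lhs <- sum(forward_project(x, g) * y)
    rhs <- sum(x * back_project(y, g))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  }
  # linearity
  x1 <- with_seed(1, matrix(rnorm(24 * 24), 24, 24))
  x2 <- with_seed(2, matrix(rnorm(24 * 24), 24, 24))
  expect_equal(forward_project(2 * x1 - 3 * x2, g),
               2 * forward_project(x1, g) - 3 * forward_project(x2, g))
  expect_identical(back_project(matrix(0, 18, g$n_detector_bins), g),
                   matrix(0, 24, 24))
})

test_that("a single-angle uniform sinogram back-projects to stripes along the ray", {
  n <- 32
  g <- acquisition_geometry(n, 0.1, 0)       # rays along +y: columns constant
  bp <- back_project(matrix(1, 1, g$n_detector_bins), g)
  interior <- bp[5:(n - 4), 5:(n - 4)]
  col_sd <- apply(interior, 2, sd)
  expect_true(all(col_sd < 1e-10))           # constant along the ray direction
  expect_gt(mean(interior), 0)
})

test_that("operator norm estimates known spectra and converges", {
  expect_equal(operator_norm(identity, identity, 16), 1, tolerance = 1e-3)
  D <- function(v) c(diff(v), 0)
  Dt <- function(p) { p[length(p)] <- 0; q <- -p
    q[-1] <- q[-1] + p[-length(p)]; q }
  nrm <- operator_norm(D, Dt, 64, n_iter = 200)
  expect_lte(nrm, 2)
  expect_gt(nrm, 1.9)                        # tends to 2 for long signals
  g <- acquisition_geometry(16, 0.2, seq(0, 360, length.out = 13)[1:12])
  n30 <- recon_operator_norm(g, 3, n_iter = 30)
  n300 <- recon_operator_norm(g, 3, n_iter = 300)
  expect_lte(n30, n300 * (1 + 1e-12))        # nondecreasing up to convergence
  expect_lt(abs(n300 - n30) / n300, 0.01)
})

test_that("FBP recovers a uniform disk and degrades gracefully when undersampled", {
  ax <- energy_axis(2, 30, 1)
  m <- material_spectrum("m", a = 0, p = 1, c = 0.5)
  ph <- build_phantom(phantom_layout(64, 0.1, m, matrix_radius = 20), ax)
  g360 <- acquisition_geometry(64, 0.1, seq(0, 360, length.out = 361)[1:360])
  sino <- forward_project(ph$volume$data, g360)
  s360 <- spectral_sinogram(sino, g360$angles, g360, ax, is_log_normalised = TRUE)
  rec <- fbp_reconstruct(s360, g360)
  interior <- rec$data[27:38, 27:38, 1]
  expect_equal(mean(interior), 0.5, tolerance = 0.02)

  # 30-angle, low-count scan shows more interior fluctuation (streaks)
  g30 <- acquisition_geometry(64, 0.1, seq(0, 360, length.out = 31)[1:30])
  pr <- scan_protocol(30, 1, source_counts_per_channel = 300, seed = 3)
  noisy <- simulate_scan(ph$volume, g30, pr)
  b30 <- negative_log(flat_field_correct(noisy$raw, noisy$flats))
  rec30 <- fbp_reconstruct(b30, g30)
  expect_gt(sd(rec30$data[27:38, 27:38, 1]), sd(interior))

  # trivial cases and preconditions
  zero <- spectral_sinogram(array(0, dim = dim(sino)), g360$angles, g360, ax,
                            is_log_normalised = TRUE)
  expect_true(all(fbp_reconstruct(zero, g360)$data == 0))
  g1 <- acquisition_geometry(64, 0.1, 0)
  s1 <- spectral_sinogram(sino[1, , , drop = FALSE], 0, g1, ax,
                          is_log_normalised = TRUE)
  expect_error(fbp_reconstruct(s1, g1), "at least 2")
})

test_that("FBP and the iterative solver agree on noiseless densely sampled data", {
  ax <- energy_axis(2, 30, 1)
  m <- material_spectrum("m", a = 0, p = 1, c = 0.4)
  ph <- build_phantom(phantom_layout(32, 0.2, m, matrix_radius = 10), ax)
  g <- acquisition_geometry(32, 0.2, seq(0, 360, length.out = 121)[1:120])
  sino <- forward_project(ph$volume$data, g)
  b <- spectral_sinogram(sino, g$angles, g, ax, is_log_normalised = TRUE)
  fbp <- fbp_reconstruct(b, g)
  nk <- recon_operator_norm(g, 2)
  p <- recon_problem(b, g, 1e-4, 1e-4, 1e-4, n_iter = 2000, gap_tol = 1e-9,
                     sigma = 0.99 / (10 * nk), tau = 0.99 * 10 / nk, norm_K = nk)
  it <- pdhg_solve(p, trace_every = 500)
  r <- roi(13, 13, 8, 8)
  m_fbp <- mean(extract_roi_spectrum(fbp, r))
  m_it <- mean(extract_roi_spectrum(it$volume, r))
  expect_lt(abs(m_fbp - m_it) / m_it, 0.05)
})
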