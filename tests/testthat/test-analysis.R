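flat_step_axis <- function(C = 30, offset = 25, slope = 0.5)
  energy_axis(C, offset, slope)

test_that("edge-step fits recover analytic step sizes", {
  ax <- flat_step_axis()
  e <- energies(ax)
  ek <- 32.2
  pre <- which(e < ek - 1); post <- which(e > ek + 1)
  # flat step 0.1 -> 0.3
  sp <- ifelse(e < ek, 0.1, 0.3)
  f <- fit_edge_step(sp, ax, ek, pre, post)
  expect_equal(f$delta_mu0, 0.2, tolerance = 1e-12)
  # sloped lines: 1 - 0.01 E below, 1.5 - 0.01 E above (slope cancels)
  sp2 <- ifelse(e < ek, 1 - 0.01 * e, 1.5 - 0.01 * e)
  expect_equal(fit_edge_step(sp2, ax, ek, pre, post)$delta_mu0, 0.5,
               tolerance = 1e-10)
  # a pure affine spectrum has no step
  sp3 <- 2 - 0.015 * e
  expect_equal(fit_edge_step(sp3, ax, ek, pre, post)$delta_mu0, 0,
               tolerance = 1e-10)
  expect_error(fit_edge_step(sp, ax, ek, pre[1], post), "at least 2")
  expect_error(fit_edge_step(sp, ax, max(e) + 1, pre, post), "strictly between")
})

test_that("the step size is invariant to adding any affine-in-energy term", {
  ax <- flat_step_axis()
  e <- energies(ax)
  ek <- 32.2
  pre <- which(e < ek - 1); post <- which(e > ek + 1)
  sp <- ifelse(e < ek, 0.1, 0.45) + 0.02 * sin(e)  # arbitrary base spectrum
  d0 <- fit_edge_step(sp, ax, ek, pre, post)$delta_mu0
  for (ab in list(c(0.3, 0), c(0, -0.02), c(-1.2, 0.05))) {
    d1 <- fit_edge_step(sp + ab[1] + ab[2] * e, ax, ek, pre, post)$delta_mu0
    expect_equal(d1, d0, tolerance = 1e-10)
  }
})

test_that("fitting simulated materials recovers their configured edge jumps", {
  # windows start 5 sigmoid-widths clear of the edge (tail < 0.7 %) and stay
  # short enough that the power-law curvature does not bias the linear
  # extrapolation beyond the percent level
  fit_preset <- function(preset, offset, ek) {
    ax <- energy_axis(60, offset = offset, slope = 0.3)
    e <- energies(ax)
    sp <- material_attenuation(preset, e)
    pre <- which(e < ek - 2 & e > ek - 5.6)
    post <- which(e > ek + 2 & e < ek + 5.6)
    fit_edge_step(sp, ax, ek, pre, post)$delta_mu0
  }
  expect_equal(fit_preset(material_presets()$iodine_tissue, 26.05, 33.169),
               0.35, tolerance = 0.01)
  expect_equal(fit_preset(material_presets()$ceria, 31.2, 40.443),
               1.0, tolerance = 0.01)
})

test_that("step-size maps are linear in tracer concentration", {
  fx <- scenes()
  truth <- fx$iodine$truth
  smap <- step_size_map(truth, 33.169)
  labels <- fx$iodine$labels
  d <- vapply(2:4, function(l) mean(smap[labels == l]), numeric(1))
  # inserts carry fractions 0.25, 0.5, 1.0 -> ratios 1 : 2 : 4
  expect_equal(d[2] / d[1], 2, tolerance = 0.02)
  expect_equal(d[3] / d[1], 4, tolerance = 0.02)
  # constant volume maps to zero
  const <- spectral_volume(array(0.3, c(6, 6, truth$axis$n_channels)), 0.1,
                           truth$axis)
  expect_equal(max(abs(step_size_map(const, 33.169))), 0, tolerance = 1e-10)
})

test_that("tracer-free step sizes stay within their propagated noise floor", {
  ax <- energy_axis(60, offset = 31.2, slope = 0.3)
  e <- energies(ax)
  base <- material_attenuation(material_presets()$aluminium, e)
  wins <- edge_windows(ax, 40.443)
  noise_sd <- 0.02
  reps <- with_seed(12, vapply(seq_len(100), function(i)
    fit_edge_step(base + rnorm(length(e), 0, noise_sd), ax, 40.443,
                  wins$pre, wins$post)$delta_mu0, numeric(1)))
  floor_est <- sd(reps)
  expect_lt(abs(fit_edge_step(base, ax, 40.443, wins$pre, wins$post)$delta_mu0),
            3 * floor_est)
  expect_lt(abs(mean(reps)), 3 * floor_est / sqrt(100) * 5)
})

test_that("edge positions are located at the straddling-channel midpoint", {
  ax <- flat_step_axis(C = 20, offset = 20, slope = 1)
  e <- energies(ax)
  sp <- ifelse(seq_along(e) <= 9, 0.2, 0.8)  # ideal step between channels 9, 10
  expect_equal(estimate_edge_position(sp, ax), (e[9] + e[10]) / 2)
  # flat and edgeless spectra are flagged absent
  expect_true(is.na(estimate_edge_position(rep(0.4, 20), ax)))
  fe <- material_attenuation(material_presets()$iron, e)
  expect_true(is.na(estimate_edge_position(fe, ax)))
  # noiseless cerium truth hits the tabulated edge within half a channel
  fx <- scenes()
  spec <- extract_roi_spectrum(fx$cerium$truth, roi(21, 39, 5, 5))
  expect_lt(abs(estimate_edge_position(spec, fx$cerium$axis) - 40.443), 0.3)
})

test_that("KES separates stained, residual and background voxels", {
  fx <- scenes()
  truth <- fx$iodine$truth
  labels <- fx$iodine$labels
  # explicit threshold below the weakest insert's signal: masks match truth
  res <- kes_segment(truth, 33.169, threshold = 0.02,
                     background_threshold = 1e9)
  expect_identical(res$stained_mask, labels >= 2L)
  expect_true(!any(res$stained_mask & res$residual_mask))
  # edgeless phantom: empty stained mask at any positive threshold
  ax <- fx$cerium$axis
  m <- material_presets()
  lay <- phantom_layout(32, 0.1, m$aluminium, inserts = list(
    list(cx = 20, cy = 12, radius = 3, material = m$iron, concentration = 1)))
  ph <- build_phantom(lay, ax)
  res0 <- kes_segment(ph$volume, 40.443, threshold = 1e-6,
                      background_threshold = 1e9)
  expect_identical(sum(res0$stained_mask), 0L)
  # bone lands in the residual mask, stained tissue does not
  lay2 <- phantom_layout(32, 0.1, m$water, inserts = list(
    list(cx = 20, cy = 12, radius = 3, material = m$iodine_tissue,
         concentration = 1),
    list(cx = 12, cy = 20, radius = 3, material = m$bone, concentration = 1)))
  ax2 <- fx$iodine$axis
  ph2 <- build_phantom(lay2, ax2)
  res2 <- kes_segment(ph2$volume, 33.169, threshold = 0.02,
                      background_threshold = 0.2)
  expect_identical(res2$stained_mask, ph2$labels == 2L)
  expect_identical(res2$residual_mask, ph2$labels == 3L)
})

test_that("the KES map tracks the fitted step-size map on noiseless data", {
  fx <- scenes()
  truth <- fx$iodine$truth
  smap <- step_size_map(truth, 33.169)
  kmap <- kes_segment(truth, 33.169, threshold = 0.02,
                      background_threshold = 1e9)$stained_map
  expect_gt(cor(as.vector(smap), as.vector(kmap)), 0.99)
})

test_that("TV-TGV segmentation beats FBP segmentation on the noisy benchmark", {
  bench <- bench_scanB()
  fx <- scenes()
  truth_labels <- fx$cerium$labels == 2L     # ceria insert
  dice <- function(mask) 2 * sum(mask & truth_labels) /
    (sum(mask) + sum(truth_labels))
  seg <- function(v) kes_segment(v, 40.443, n_side_channels = 5,
                                 threshold = 0.3, background_threshold = 1e9)
  expect_gt(dice(seg(bench$tvtgv$volume)$stained_mask),
            dice(seg(bench$fbp)$stained_mask))
})
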