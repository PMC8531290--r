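make_raw <- function(data, C = 2) {
  ax <- energy_axis(C, 30, 1)
  spectral_sinogram(data, seq_len(dim(data)[1]), NULL, ax)
}

test_that("flat-field correction produces clipped transmission", {
  C <- 2; nb <- 6; na <- 3
  flat <- array(1000, c(1, nb, C))
  raw <- make_raw(array(1000, c(na, nb, C)), C)
  t1 <- flat_field_correct(raw, flat)
  expect_true(all(t1$data == 1))             # raw = flat, dark = 0
  t0 <- flat_field_correct(make_raw(array(0, c(na, nb, C)), C), flat)
  expect_true(all(t0$data == 1e-6))          # photon starvation floor
  th <- flat_field_correct(make_raw(array(500, c(na, nb, C)), C), flat)
  expect_true(all(th$data == 0.5))
})

test_that("flat-field correction is scale invariant and flags dead pixels", {
  C <- 3; nb <- 5; na <- 4
  flat <- array(with_seed(8, runif(nb * C, 800, 1200)), c(1, nb, C))
  rawd <- array(with_seed(9, runif(na * nb * C, 100, 700)), c(na, nb, C))
  t1 <- flat_field_correct(make_raw(rawd, C), flat)
  t2 <- flat_field_correct(make_raw(3 * rawd, C), 3 * flat)
  expect_equal(t1$data, t2$data)
  # dead pixel: flat below dark gets imputed from neighbouring channels
  dark <- array(10, c(1, nb, C))
  flat_bad <- flat; flat_bad[1, 2, 2] <- 5
  tb <- flat_field_correct(make_raw(rawd, C), flat_bad, dark)
  mask <- attr(tb, "bad_pixel_mask")
  expect_true(mask[2, 2] && sum(mask) == 1)
  expect_true(all(is.finite(tb$data)))
})

test_that("negative log linearises transmission", {
  C <- 2
  tr <- make_raw(array(c(1, exp(-1)), c(2, 1, C)), C)
  b <- negative_log(tr)
  expect_equal(b$data[1, 1, ], c(0, 0))
  expect_equal(b$data[2, 1, ], c(1, 1))
  expect_true(b$is_log_normalised)
  bad <- make_raw(array(1, c(2, 1, C)), C); bad$data[1] <- 0
  expect_error(negative_log(bad), "non-positive")
})

ring_sino <- function(with_ring = FALSE, na = 64, nb = 64, C = 2) {
  ax <- energy_axis(C, 30, 1)
  base <- outer(1.5 + sin(seq(0, 2 * pi, length.out = na)),
                exp(-((seq_len(nb) - nb / 2)^2) / (2 * 20^2)))
  arr <- array(rep(base, C), c(na, nb, C))
  if (with_ring) arr[, 25, ] <- arr[, 25, ] + 0.2   # stripe constant in angle
  spectral_sinogram(arr, seq_len(na), NULL, ax, is_log_normalised = TRUE)
}

# amplitude of the fixed-pattern offset at detector bin j: its mean contrast
# against the neighbouring bins (the quantity that reconstructs into a ring)
stripe_contrast <- function(s, j) {
  m <- apply(s$data, 2, mean)
  m[j] - (m[j - 1] + m[j + 1]) / 2
}

test_that("wavelet-Fourier filter removes ring stripes and little else", {
  clean <- ring_sino(FALSE)
  ringed <- ring_sino(TRUE)
  # sigma = 0 is the exact identity
  expect_equal(remove_rings_wavelet_fourier(ringed, sigma = 0)$data, ringed$data)
  # near-identity on ring-free data
  f_clean <- remove_rings_wavelet_fourier(clean, levels = 3, sigma = 2)
  rel_rms <- sqrt(mean((f_clean$data - clean$data)^2)) /
    sqrt(mean(clean$data^2))
  expect_lt(rel_rms, 0.01)
  # the synthetic stripe's amplitude is attenuated at least tenfold
  f_ring <- remove_rings_wavelet_fourier(ringed, levels = 3, sigma = 2)
  expect_gt(abs(stripe_contrast(ringed, 25)), 10 * abs(stripe_contrast(f_ring, 25)))
  expect_error(remove_rings_wavelet_fourier(ringed, levels = 8), "depth")
  raw <- ring_sino(TRUE); raw$is_log_normalised <- FALSE
  expect_error(remove_rings_wavelet_fourier(raw), "log-normalised")
})

test_that("ring filtering is strictly channel-wise (commutes with subsetting)", {
  s <- ring_sino(TRUE, C = 4)
  a <- select_channel_range(remove_rings_wavelet_fourier(s, levels = 3), 2, 3)
  b <- remove_rings_wavelet_fourier(select_channel_range(s, 2, 3), levels = 3)
  expect_equal(a$data, b$data, tolerance = 1e-12)
})
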