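# Forward-difference operators with Neumann (replicate) boundary on
# row x col x channel arrays, and their exact adjoints (negative divergence).
# The last difference along each direction is zero, so constant signals map
# to zero; adjointness <D x, p> == <x, D^T p> holds to machine precision and
# is what the saddle-point solver relies on.

dx_fwd <- function(u) {
  n <- dim(u)[1L]
  d <- u
  d[-n, , ] <- u[-1L, , , drop = FALSE] - u[-n, , , drop = FALSE]
  d[n, , ] <- 0
  d
}

dx_adj <- function(p) {
  n <- dim(p)[1L]
  q <- p; q[n, , ] <- 0
  out <- -q
  out[-1L, , ] <- out[-1L, , , drop = FALSE] + q[-n, , , drop = FALSE]
  out
}

dy_fwd <- function(u) {
  n <- dim(u)[2L]
  d <- u
  d[, -n, ] <- u[, -1L, , drop = FALSE] - u[, -n, , drop = FALSE]
  d[, n, ] <- 0
  d
}

dy_adj <- function(p) {
  n <- dim(p)[2L]
  q <- p; q[, n, ] <- 0
  out <- -q
  out[, -1L, ] <- out[, -1L, , drop = FALSE] + q[, -n, , drop = FALSE]
  out
}

dc_fwd <- function(u) {
  n <- dim(u)[3L]
  d <- u
  if (n > 1L) d[, , -n] <- u[, , -1L, drop = FALSE] - u[, , -n, drop = FALSE]
  d[, , n] <- 0
  d
}

dc_adj <- function(p) {
  n <- dim(p)[3L]
  q <- p; q[, , n] <- 0
  out <- -q
  if (n > 1L) out[, , -1L] <- out[, , -1L, drop = FALSE] + q[, , -n, drop = FALSE]
  out
}

# The spectral-TGV slope field w lives on the staggered difference grid: only
# its first n_channels - 1 entries are meaningful (entry i pairs with the
# difference u[i+1] - u[i]).  mask_lastc zeroes the unused trailing slot so
# that D_c u - w has no spurious boundary component and affine spectra give
# a TGV value of exactly zero.

mask_lastc <- function(w) {
  w[, , dim(w)[3L]] <- 0
  w
}

# forward difference of the slope field on its own (length n-1) grid: entries
# i <= n - 2 are w[i+1] - w[i]; the two trailing slots are structurally zero
dc2_fwd <- function(w) {
  n <- dim(w)[3L]
  d <- dc_fwd(w)
  if (n > 1L) d[, , n - 1L] <- 0
  d
}

dc2_adj <- function(p) {
  n <- dim(p)[3L]
  q <- p
  if (n > 1L) q[, , n - 1L] <- 0
  dc_adj(q)
}
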