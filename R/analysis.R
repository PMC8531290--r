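#' Fit the absorption-edge step size of a voxel spectrum
#'
#' Ordinary least-squares lines in (keV, attenuation) are fitted to a window
#' of channels before the edge and a window after it; extrapolating both to
#' the known edge energy and differencing gives the step size
#' `delta_mu0 = post_line(E_K) - pre_line(E_K)`, which is directly
#' proportional to the local concentration of the edge-bearing element.  The
#' value may be negative on noisy spectra; it is deliberately not clipped.
#'
#' @param spectrum Per-channel attenuation vector (mm^-1).
#' @param axis The matching [energy_axis()].
#' @param edge_energy Known K-edge energy, keV, strictly between the windows.
#' @param pre_window,post_window Integer vectors of channel elements
#'   (1-based) to fit on; each needs >= 2 channels and must lie strictly
#'   below / above the edge energy.
#' @return An object of class `edge_fit`: list with `pre_slope`,
#'   `pre_intercept`, `post_slope`, `post_intercept`, `delta_mu0`,
#'   `edge_energy`, `pre_window`, `post_window`.
#' @export
fit_edge_step <- function(spectrum, axis, edge_energy, pre_window, post_window) {
  stopifnot(inherits(axis, "energy_axis"))
  if (length(spectrum) != axis$n_channels)
    stop("spectrum length != axis$n_channels")
  pre_window <- as.integer(pre_window); post_window <- as.integer(post_window)
  if (length(pre_window) < 2L || length(post_window) < 2L)
    stop("each fit window needs at least 2 channels")
  if (any(pre_window < 1L) || any(post_window > axis$n_channels))
    stop("fit window outside the channel range")
  e <- energies(axis)
  if (max(e[pre_window]) >= edge_energy || min(e[post_window]) <= edge_energy)
    stop("edge_energy must lie strictly between the two fit windows")
  pre <- stats::lm.fit(cbind(1, e[pre_window]), spectrum[pre_window])$coefficients
  post <- stats::lm.fit(cbind(1, e[post_window]), spectrum[post_window])$coefficients
  structure(
    list(pre_intercept = unname(pre[1L]), pre_slope = unname(pre[2L]),
         post_intercept = unname(post[1L]), post_slope = unname(post[2L]),
         delta_mu0 = unname((post[1L] + post[2L] * edge_energy) -
                            (pre[1L] + pre[2L] * edge_energy)),
         edge_energy = edge_energy,
         pre_window = pre_window, post_window = post_window),
    class = "edge_fit"
  )
}

#' @export
print.edge_fit <- function(x, ...) {
  cat(sprintf("<edge_fit> delta_mu0 = %.4g mm^-1 at E_K = %.3f keV\n",
              x$delta_mu0, x$edge_energy))
  cat(sprintf("  pre:  mu = %.4g %+.4g E (channels %d..%d)\n", x$pre_intercept,
              x$pre_slope, min(x$pre_window), max(x$pre_window)))
  cat(sprintf("  post: mu = %.4g %+.4g E (channels %d..%d)\n", x$post_intercept,
              x$post_slope, min(x$post_window), max(x$post_window)))
  invisible(x)
}

#' Default fit windows either side of an edge
#'
#' Chooses `n_side` channels each side of the edge, separated from it by an
#' exclusion zone covering the detector-broadened transition (default: 2
#' channels either side).
#'
#' @param axis An [energy_axis()].
#' @param edge_energy Edge energy, keV.
#' @param n_side Channels per window (default 10).
#' @param exclusion Channels excluded next to the edge on each side (default 2).
#' @return List with integer vectors `pre` and `post`.
#' @export
edge_windows <- function(axis, edge_energy, n_side = 10, exclusion = 2) {
  e <- energies(axis)
  below <- which(e < edge_energy)
  above <- which(e > edge_energy)
  if (length(below) < exclusion + 2L || length(above) < exclusion + 2L)
    stop("edge too close to the channel-range boundary for these windows")
  pre <- utils::tail(utils::head(below, length(below) - exclusion), n_side)
  post <- utils::head(utils::tail(above, length(above) - exclusion), n_side)
  if (length(pre) < 2L || length(post) < 2L)
    stop("not enough channels for the fit windows")
  list(pre = pre, post = post)
}

#' Per-voxel edge step-size map
#'
#' Repeats [fit_edge_step()] at every voxel of a reconstructed volume,
#' producing a 2D map of `delta_mu0` — a relative concentration map of the
#' edge-bearing element.  Linear least squares over fixed windows is a linear
#' functional of the spectrum, so the map is computed with two precomputed
#' weight vectors applied across the channel dimension.
#'
#' @param v A [spectral_volume()].
#' @param edge_energy K-edge energy, keV.
#' @param pre_window,post_window Channel windows as in [fit_edge_step()];
#'   `NULL` picks [edge_windows()] defaults.
#' @return Numeric matrix (row x col) of `delta_mu0` values, mm^-1.
#' @export
step_size_map <- function(v, edge_energy, pre_window = NULL, post_window = NULL) {
  stopifnot(inherits(v, "spectral_volume"))
  if (is.null(pre_window) || is.null(post_window)) {
    wins <- edge_windows(v$axis, edge_energy)
    if (is.null(pre_window)) pre_window <- wins$pre
    if (is.null(post_window)) post_window <- wins$post
  }
  e <- energies(v$axis)
  # OLS evaluated at E_K is a linear functional: value = sum(wt * spectrum)
  eval_weights <- function(win) {
    X <- cbind(1, e[win])
    H <- solve(crossprod(X), t(X))           # 2 x |win|: (intercept, slope)
    as.vector(c(1, edge_energy) %*% H)
  }
  # validate via the scalar path (errors on bad windows)
  fit_edge_step(v$data[1L, 1L, ], v$axis, edge_energy, pre_window, post_window)
  w_pre <- eval_weights(pre_window)
  w_post <- eval_weights(post_window)
  d <- dim(v$data)
  um <- matrix(v$data, d[1L] * d[2L], d[3L])
  map <- um[, post_window, drop = FALSE] %*% w_post -
    um[, pre_window, drop = FALSE] %*% w_pre
  matrix(map, d[1L], d[2L])
}

#' Estimate the position of an absorption edge in a spectrum
#'
#' Locates the maximum forward difference of the (optionally moving-average
#' smoothed) spectrum and reports the edge at the midpoint between the two
#' straddling channel centres.  If the largest derivative does not stand out
#' from the spectrum's baseline variation (below `significance` times the
#' median absolute forward difference), no edge is declared and `NA` is
#' returned.
#'
#' @param spectrum Per-channel attenuation vector (>= 5 channels).
#' @param axis The matching [energy_axis()].
#' @param smoothing Moving-average window in channels (default 1: none).
#' @param significance Detection threshold as a multiple of the median
#'   absolute forward difference (default 5).
#' @return Edge energy in keV, or `NA_real_` if no significant edge exists.
#' @export
estimate_edge_position <- function(spectrum, axis, smoothing = 1,
                                   significance = 5) {
  stopifnot(inherits(axis, "energy_axis"))
  if (length(spectrum) != axis$n_channels)
    stop("spectrum length != axis$n_channels")
  if (length(spectrum) < 5L) stop("need at least 5 channels")
  s <- spectrum
  if (smoothing > 1) {
    k <- rep(1 / smoothing, smoothing)
    s <- as.vector(stats::filter(spectrum, k, sides = 2))
    s[is.na(s)] <- spectrum[is.na(s)]        # keep the ends unsmoothed
  }
  d <- diff(s)
  i <- which.max(d)
  med <- stats::median(abs(d))
  if (d[i] <= 0 || (med > 0 && d[i] < significance * med)) return(NA_real_)
  e <- energies(axis)
  (e[i] + e[i + 1L]) / 2
}

#' K-edge subtraction segmentation
#'
#' Classic KES: average a set of channels just below the edge and an
#' equivalent set just above it, subtract, and threshold.  Voxels whose
#' post-minus-pre difference exceeds the threshold contain the edge-bearing
#' (stained) material; of the rest, voxels whose pre-edge attenuation exceeds
#' a background level form the residual ("remaining material") mask — e.g.
#' hydroxyapatite bone, which attenuates strongly but has no edge in range.
#'
#' @param v A [spectral_volume()].
#' @param edge_energy K-edge energy, keV.
#' @param n_side_channels Channels averaged on each side (default 5).
#' @param exclusion Channels excluded around the edge on each side (default 2,
#'   covering the detector-broadened transition).
#' @param threshold Stained-map threshold (mm^-1), or `"otsu"` (default) to
#'   derive it from the stained-map histogram.
#' @param background_threshold Pre-edge attenuation above which an unstained
#'   voxel counts as residual material, or `"otsu"` (default).
#' @return An object of class `kes_result`: list with `stained_map` (matrix,
#'   post mean - pre mean), `stained_mask`, `residual_mask` (disjoint logical
#'   matrices), `threshold`, `background_threshold`, `pre_window`,
#'   `post_window`.
#' @export
kes_segment <- function(v, edge_energy, n_side_channels = 5, exclusion = 2,
                        threshold = "otsu", background_threshold = "otsu") {
  stopifnot(inherits(v, "spectral_volume"))
  if (n_side_channels < 1) stop("n_side_channels must be >= 1")
  wins <- edge_windows(v$axis, edge_energy, n_side = n_side_channels,
                       exclusion = exclusion)
  e <- energies(v$axis)
  # windows must not touch the exclusion zone
  excl <- abs(e - edge_energy) <= exclusion * v$axis$slope
  if (any(excl[c(wins$pre, wins$post)]))
    stop("fit windows overlap the exclusion zone")
  d <- dim(v$data)
  um <- matrix(v$data, d[1L] * d[2L], d[3L])
  pre_mean <- rowMeans(um[, wins$pre, drop = FALSE])
  post_mean <- rowMeans(um[, wins$post, drop = FALSE])
  smap <- matrix(post_mean - pre_mean, d[1L], d[2L])
  pre_img <- matrix(pre_mean, d[1L], d[2L])
  if (identical(threshold, "otsu")) threshold <- otsu_threshold(smap)
  if (identical(background_threshold, "otsu"))
    background_threshold <- otsu_threshold(pre_img)
  stained <- smap > threshold
  residual <- !stained & (pre_img > background_threshold)
  structure(
    list(stained_map = smap, stained_mask = stained, residual_mask = residual,
         threshold = threshold, background_threshold = background_threshold,
         pre_window = wins$pre, post_window = wins$post),
    class = "kes_result"
  )
}

#' @export
print.kes_result <- function(x, ...) {
  cat(sprintf("<kes_result> %d stained voxels, %d residual voxels (threshold %.4g, background %.4g)\n",
              sum(x$stained_mask), sum(x$residual_mask), x$threshold,
              x$background_threshold))
  invisible(x)
}

# Otsu's threshold on an arbitrary-range image (EBImage works on [0, 1])
otsu_threshold <- function(img) {
  rng <- range(img)
  if (diff(rng) == 0) return(rng[1L])
  scaled <- (img - rng[1L]) / diff(rng)
  t01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  rng[1L] + t01 * diff(rng)
}
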