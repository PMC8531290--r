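#' Channel-wise contrast-to-noise ratio with channel-averaged noise
#'
#' CNR between a signal and a background ROI, computed per energy channel.
#' Spatial variation is averaged by using ROIs of several voxels (5x5 is
#' typical); spectral fluctuation of the noise estimate is averaged by taking
#' each ROI's standard deviation per channel, averaging it over all channels,
#' and using that channel-averaged value in every channel's CNR:
#'
#'   CNR(c) = |m_S(c) - m_B(c)| / pool(sd_S_bar, sd_B_bar)
#'
#' where `pool` is quadrature `sqrt(s^2 + b^2)` (default) or the arithmetic
#' mean `(s + b) / 2` — both forms are in use in the CT literature, so the
#' variant is selectable.
#'
#' @param v A [spectral_volume()].
#' @param roi_signal,roi_background Disjoint [roi()]s, each at least 2x2.
#' @param pooling `"quadrature"` (default) or `"mean"`.
#' @return List with `cnr` (per-channel vector; `Inf` channels are possible
#'   if the pooled noise is zero), `average` (mean over finite channels; a
#'   warning is raised and infinite channels excluded if the pooled noise
#'   vanishes), `noise_signal`, `noise_background` (the channel-averaged
#'   standard deviations).
#' @export
cnr_channelwise <- function(v, roi_signal, roi_background,
                            pooling = c("quadrature", "mean")) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(v, "spectral_volume"))
  d <- dim(v$data)
  roi_check(roi_signal, d); roi_check(roi_background, d)
  if (roi_signal$rows < 2L || roi_signal$cols < 2L ||
      roi_background$rows < 2L || roi_background$cols < 2L)
    stop("CNR ROIs must be at least 2x2")
  if (rois_overlap(roi_signal, roi_background))
    stop("signal and background ROIs must be disjoint")
  S <- v$data[roi_rows(roi_signal), roi_cols(roi_signal), , drop = FALSE]
  B <- v$data[roi_rows(roi_background), roi_cols(roi_background), , drop = FALSE]
  m_s <- apply(S, 3L, mean); m_b <- apply(B, 3L, mean)
  sd_s <- mean(apply(S, 3L, stats::sd))      # channel-averaged ROI sd
  sd_b <- mean(apply(B, 3L, stats::sd))
  noise <- switch(pooling,
                  quadrature = sqrt(sd_s^2 + sd_b^2),
                  mean = (sd_s + sd_b) / 2)
  if (noise == 0) {
    warning("pooled noise estimate is zero; CNR is infinite")
    cnr <- ifelse(abs(m_s - m_b) > 0, Inf, NaN)
  } else {
    cnr <- abs(m_s - m_b) / noise
  }
  list(cnr = cnr, average = mean(cnr[is.finite(cnr)]),
       noise_signal = sd_s, noise_background = sd_b)
}

rois_overlap <- function(a, b) {
  !(a$row + a$rows - 1L < b$row || b$row + b$rows - 1L < a$row ||
    a$col + a$cols - 1L < b$col || b$col + b$cols - 1L < a$col)
}

#' Channel-wise RMSE against a reference volume
#'
#' For each energy channel, the voxel-wise residuals between a volume and a
#' reference over an ROI are squared, averaged and square-rooted.
#'
#' @param v,reference [spectral_volume()]s on the same grid and energy axis.
#' @param r A [roi()] inside the grid.
#' @return Per-channel RMSE vector (>= 0; 0 iff equal on the ROI).
#' @export
rmse_channelwise <- function(v, reference, r) {
  stopifnot(inherits(v, "spectral_volume"), inherits(reference, "spectral_volume"))
  if (!all(dim(v$data) == dim(reference$data)))
    stop("volume and reference shapes differ")
  ax <- v$axis; rx <- reference$axis
  if (ax$n_channels != rx$n_channels || ax$offset != rx$offset ||
      ax$slope != rx$slope)
    stop("energy axes differ between volume and reference")
  roi_check(r, dim(v$data))
  dv <- v$data[roi_rows(r), roi_cols(r), , drop = FALSE] -
    reference$data[roi_rows(r), roi_cols(r), , drop = FALSE]
  sqrt(apply(dv^2, 3L, mean))
}

#' Percentage improvement of one metric over another
#'
#' @param metric_a Improved value.
#' @param metric_b Baseline value; must be non-zero.
#' @return `100 * (metric_a - metric_b) / metric_b`, percent.
#' @examples
#' improvement_percent(38.26, 7.81)  # ~390
#' @export
improvement_percent <- function(metric_a, metric_b) {
  if (any(metric_b == 0)) stop("baseline metric is zero")
  100 * (metric_a - metric_b) / metric_b
}
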