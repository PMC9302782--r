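#' Perturbation RMS by Reynolds decomposition
#'
#' Splits each point's velocity-magnitude signal over the cycle into a
#' slow trend and high-frequency perturbations, and returns the RMS of the
#' perturbation. The trend is a zero-phase low-pass of the periodic
#' signal, implemented as an FFT brick-wall filter: Fourier components at
#' or below `trend_cutoff` are the trend, everything above is
#' perturbation. The default cutoff of 15 Hz keeps cardiac-scale harmonics
#' in the trend while transitional-flow oscillations (tens of Hz) land
#' entirely in the perturbation band.
#'
#' @param series an [velocity_field_series()] spanning one cycle.
#' @param trend_cutoff trend/perturbation separation frequency, Hz.
#' @return numeric vector, m/s: perturbation RMS per sample point.
#' @export
reynolds_rms <- function(series, trend_cutoff = 15) {
  stopifnot(inherits(series, "avg_velocity_field"))
  check_positive(trend_cutoff, "trend_cutoff")
  u <- series$u
  n <- nrow(u)
  nyquist <- n / (2 * series$period)
  if (trend_cutoff >= nyquist)
    stopf("trend cutoff %.3g Hz is at or above the Nyquist frequency %.3g Hz",
          trend_cutoff, nyquist)
  if (series$period < 1 / trend_cutoff)
    stopf("cycle too short to resolve the trend band")
  freq <- (seq_len(n) - 1L) / series$period
  freq <- pmin(freq, n / series$period - freq)   # fold to [0, Nyquist]
  keep <- freq <= trend_cutoff + 1e-12
  uh <- stats::mvfft(u)
  uh[!keep, ] <- 0
  trend <- Re(stats::mvfft(uh, inverse = TRUE)) / n
  sqrt(colMeans((u - trend)^2))
}

#' Cross-sectional median perturbation profile
#'
#' Collapses a per-point perturbation-RMS field onto a centerline profile:
#' points are assigned to equally spaced stations along the branch by
#' nearest-centerline-point projection, and each station reports the
#' median RMS of the points within half a station spacing of its plane.
#' The median is deliberately robust to the few very high values inside a
#' jet core. Stations with no points are returned as `NA` (missing).
#'
#' @param rms numeric vector, m/s (e.g. from [reynolds_rms()]).
#' @param points `n x 3` matrix of the sample-point coordinates, mm.
#' @param branch a centerline branch (list with `points` and `arc`), e.g.
#'   `tree$branches$vein`.
#' @param station_spacing distance between stations, mm.
#' @return data frame with `s` (arc length, mm), `u_rms_50` (m/s) and
#'   `n_points` per station.
#' @export
cross_sectional_median_profile <- function(rms, points, branch,
                                           station_spacing = 5) {
  if (length(rms) != nrow(points))
    stopf("'rms' and 'points' disagree in length")
  check_positive(station_spacing, "station_spacing")
  cl <- branch$points
  s_of_point <- vapply(seq_len(nrow(points)), function(i) {
    d2 <- colSums((t(cl) - points[i, ])^2)
    branch$arc[which.min(d2)]
  }, numeric(1))
  stations <- seq(0, max(branch$arc), by = station_spacing)
  med <- rep(NA_real_, length(stations))
  cnt <- integer(length(stations))
  for (k in seq_along(stations)) {
    in_slab <- abs(s_of_point - stations[k]) <= station_spacing / 2
    cnt[k] <- sum(in_slab)
    if (cnt[k] > 0) med[k] <- stats::median(rms[in_slab])
  }
  data.frame(s = stations, u_rms_50 = med, n_points = cnt)
}
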