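#' Synthetic WSS field fixtures with known metric values
#'
#' Generates WSS field time-series whose TAWSS, peak WSS and OSI are known
#' in closed form, for exercising the metric suite without CFD output:
#' \describe{
#'   \item{constant}{`tau = A d` fixed: TAWSS = WSS_max = A, OSI = 0.}
#'   \item{sinusoid}{`tau = A sin(2 pi t / T) d`: zero-mean single-axis
#'     oscillation, OSI = 0.5 exactly, TAWSS = 2A/pi (continuous limit),
#'     WSS_max = A.}
#'   \item{reversing}{`+A d` for 3T/4 then `-A d` for T/4: OSI = 0.25,
#'     TAWSS = A (n_t is forced to a multiple of 4 so the discrete values
#'     are exact).}
#'   \item{mixed_region}{two-level constant field arranged so that a
#'     prescribed fraction of the total area exceeds the high-WSS
#'     threshold.}
#' }
#' All generators are seed-deterministic; the returned `truth` element
#' records the generator parameters and exact expected values.
#'
#' @param pattern fixture pattern (see above).
#' @param n_points number of sample points.
#' @param n_t time samples per cycle.
#' @param period cycle duration, s.
#' @param amplitude WSS scale `A`, Pa.
#' @param seed RNG seed (point areas and directions).
#' @param frac_high for `mixed_region`: target area fraction (0-1) above
#'   `high_level`.
#' @param high_level,low_level mixed-region WSS levels, Pa.
#' @return list with `field` (an [wss_field_series()]) and `truth`.
#' @export
make_wss_fixture <- function(pattern = c("constant", "sinusoid",
                                         "reversing", "mixed_region"),
                             n_points = 200L, n_t = 64L, period = 1.0,
                             amplitude = 5, seed = 1L, frac_high = 0.3,
                             high_level = 10, low_level = 1) {
  pattern <- match.arg(pattern)
  with_seed(seed, {
    areas <- stats::runif(n_points, 0.5, 1.5) * 1e-6
    dirs <- matrix(stats::rnorm(n_points * 3L), n_points, 3L)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    t_open <- seq(0, period, length.out = n_t + 1L)[seq_len(n_t)]
    tau <- array(0, dim = c(n_t, n_points, 3L))
    truth <- list(pattern = pattern, amplitude = amplitude, seed = seed,
                  period = period)

    if (pattern == "constant") {
      for (k in 1:3) tau[, , k] <- matrix(amplitude * dirs[, k], n_t,
                                          n_points, byrow = TRUE)
      truth$tawss <- rep(amplitude, n_points)
      truth$wss_max <- rep(amplitude, n_points)
      truth$osi <- rep(0, n_points)
    } else if (pattern == "sinusoid") {
      sgn <- sin(2 * pi * t_open / period)
      for (k in 1:3) tau[, , k] <- outer(sgn, amplitude * dirs[, k])
      truth$tawss <- rep(2 * amplitude / pi, n_points)
      truth$wss_max <- rep(amplitude, n_points)
      truth$osi <- rep(0.5, n_points)
    } else if (pattern == "reversing") {
      n_t <- 4L * ceiling(n_t / 4L)
      t_open <- seq(0, period, length.out = n_t + 1L)[seq_len(n_t)]
      tau <- array(0, dim = c(n_t, n_points, 3L))
      sgn <- ifelse(t_open < 0.75 * period, 1, -1)
      for (k in 1:3) tau[, , k] <- outer(sgn, amplitude * dirs[, k])
      truth$tawss <- rep(amplitude, n_points)
      truth$wss_max <- rep(amplitude, n_points)
      truth$osi <- rep(0.25, n_points)
    } else {                              # mixed_region
      m <- max(1L, round(n_points / 3))
      hi <- seq_len(m)
      # rescale the high-group areas so they hold exactly frac_high of
      # the total area
      s_hi <- sum(areas[hi]); s_lo <- sum(areas[-hi])
      areas[hi] <- areas[hi] * frac_high * s_lo / ((1 - frac_high) * s_hi)
      level <- ifelse(seq_len(n_points) %in% hi, high_level, low_level)
      for (k in 1:3) tau[, , k] <- matrix(level * dirs[, k], n_t,
                                          n_points, byrow = TRUE)
      truth$tawss <- level
      truth$wss_max <- level
      truth$osi <- rep(0, n_points)
      truth$frac_high_percent <- 100 * frac_high
      truth$high_points <- hi
    }
    list(field = wss_field_series(tau, areas, period), truth = truth)
  })
}

#' Synthetic velocity fixtures with known perturbation RMS
#'
#' Builds a tube of volume sample points (uniform axial stations, random
#' cross-sectional scatter) carrying a slow common velocity trend plus a
#' high-frequency perturbation of exactly known per-point RMS. The
#' per-station RMS follows the requested axial profile, so the recovered
#' cross-sectional median profile has a known ground truth.
#'
#' Perturbations: `"sinusoid"` injects `amp sin(2 pi f t + phase_i)` at
#' `perturbation_freq` (RMS = amp/sqrt(2) exactly in the continuous
#' limit); `"band_noise"` injects Gaussian noise band-limited to
#' `band` and rescaled per point to the exact target RMS.
#'
#' @param profile numeric vector: target perturbation RMS (m/s) per axial
#'   station, or a single value for a flat profile.
#' @param n_stations axial stations (length of the tube grid); ignored if
#'   `profile` is a vector.
#' @param n_per points per station.
#' @param tube_length tube length, mm.
#' @param n_t time samples per cycle.
#' @param period cycle duration, s.
#' @param trend list: `base` (m/s), `amp` (m/s), `freq` (Hz) of the slow
#'   trend.
#' @param perturbation `"band_noise"` or `"sinusoid"`.
#' @param perturbation_freq sinusoid frequency, Hz.
#' @param band band-noise frequency range, Hz.
#' @param seed RNG seed.
#' @return list with `series` (an [velocity_field_series()]) and `truth`
#'   (per-point target RMS, station coordinates, profile).
#' @export
make_velocity_fixture <- function(profile = 0.1, n_stations = 20L,
                                  n_per = 30L, tube_length = 100,
                                  n_t = 256L, period = 1.0,
                                  trend = list(base = 0.5, amp = 0.2,
                                               freq = 1),
                                  perturbation = c("band_noise", "sinusoid"),
                                  perturbation_freq = 40,
                                  band = c(35, 45), seed = 1L) {
  perturbation <- match.arg(perturbation)
  if (length(profile) > 1L) n_stations <- length(profile)
  prof <- rep_len(profile, n_stations)
  nyquist <- n_t / (2 * period)
  if (perturbation == "band_noise" && band[2] >= nyquist)
    stopf("band upper edge %.3g Hz at or above Nyquist %.3g Hz",
          band[2], nyquist)
  if (perturbation == "sinusoid" && perturbation_freq >= nyquist)
    stopf("perturbation frequency above Nyquist")

  with_seed(seed, {
    s_stations <- seq(0, tube_length, length.out = n_stations)
    n_p <- n_stations * n_per
    station_of <- rep(seq_len(n_stations), each = n_per)
    radius <- 3
    ang <- stats::runif(n_p, 0, 2 * pi)
    rad <- radius * sqrt(stats::runif(n_p))
    points <- cbind(s_stations[station_of], rad * cos(ang), rad * sin(ang))
    t_open <- seq(0, period, length.out = n_t + 1L)[seq_len(n_t)]
    base_trend <- trend$base + trend$amp * sin(2 * pi * trend$freq * t_open)
    target <- prof[station_of]

    u <- matrix(base_trend, n_t, n_p)
    if (perturbation == "sinusoid") {
      phase <- stats::runif(n_p, 0, 2 * pi)
      amp <- target * sqrt(2)
      for (j in seq_len(n_p))
        u[, j] <- u[, j] +
          amp[j] * sin(2 * pi * perturbation_freq * t_open + phase[j])
    } else {
      freq <- (seq_len(n_t) - 1L) / period
      freq <- pmin(freq, n_t / period - freq)
      in_band <- freq >= band[1] & freq <= band[2]
      noise <- matrix(stats::rnorm(n_t * n_p), n_t, n_p)
      nh <- stats::mvfft(noise)
      nh[!in_band, ] <- 0
      pert <- Re(stats::mvfft(nh, inverse = TRUE)) / n_t
      rms0 <- sqrt(colMeans(pert^2))
      scale <- ifelse(rms0 > 0, target / pmax(rms0, 1e-300), 0)
      u <- u + pert * matrix(scale, n_t, n_p, byrow = TRUE)
    }
    truth <- list(profile = prof, stations = s_stations,
                  target_rms = target, station_of = station_of,
                  trend = trend, perturbation = perturbation, seed = seed)
    list(series = velocity_field_series(u, period, points), truth = truth)
  })
}

#' Synthetic centerline trees with recorded junction truth
#'
#' `"idealized_loop"` is the parametrized idealized build itself;
#' `"tortuous_realistic"` applies a smooth, seed-deterministic sinusoidal
#' warp to all branches simultaneously (so the branches still meet at
#' their anastomoses), emulating the tortuosity of an imaged patient
#' circuit. With `curvature_amplitude = 0` the tortuous style reduces to
#' the idealized loop. The returned `truth` records the exact post-warp
#' junction coordinates.
#'
#' @param style `"idealized_loop"` or `"tortuous_realistic"`.
#' @param specs,anastomoses,graft_path,spacing passed to
#'   [build_idealized_centerlines()].
#' @param curvature_amplitude warp displacement amplitude, mm.
#' @param wavelength warp wavelength, mm.
#' @param seed RNG seed for the warp phases.
#' @return list with `tree` (an [centerline_tree()]) and `truth`
#'   (junction coordinates).
#' @export
make_toy_centerlines <- function(style = c("idealized_loop",
                                           "tortuous_realistic"),
                                 specs = default_vessel_specs(),
                                 anastomoses = list(
                                   arterial = anastomosis_spec(45),
                                   venous = anastomosis_spec(45)),
                                 graft_path = list(),
                                 curvature_amplitude = 3, wavelength = 60,
                                 spacing = 0.25, seed = 1L) {
  style <- match.arg(style)
  tree <- build_idealized_centerlines(specs, anastomoses, graft_path,
                                      spacing)
  if (style == "idealized_loop" || curvature_amplitude == 0)
    return(list(tree = tree,
                truth = list(junctions = lapply(tree$junctions, `[[`,
                                                "point"))))
  phases <- with_seed(seed, stats::runif(6, 0, 2 * pi))
  warp <- function(p) {
    cbind(p[, 1] + curvature_amplitude *
            sin(2 * pi * p[, 2] / wavelength + phases[1]) *
            sin(2 * pi * p[, 3] / wavelength + phases[2]),
          p[, 2] + curvature_amplitude *
            sin(2 * pi * p[, 1] / wavelength + phases[3]),
          p[, 3] + curvature_amplitude *
            sin(2 * pi * (p[, 1] + p[, 2]) / wavelength + phases[4]))
  }
  specs <- as_spec_list(specs)
  branches <- lapply(names(tree$branches), function(nm) {
    b <- tree$branches[[nm]]
    make_branch(warp(b$points), specs[[nm]]$diameter / 2, spacing)
  })
  names(branches) <- names(tree$branches)
  junctions <- tree$junctions
  for (nm in names(junctions)) {
    jp <- drop(warp(matrix(junctions[[nm]]$point, 1, 3)))
    host <- branches[[junctions[[nm]]$host]]
    graft <- branches$graft
    junctions[[nm]]$point <- jp
    junctions[[nm]]$host_s <-
      host$arc[which.min(colSums((t(host$points) - jp)^2))]
    junctions[[nm]]$graft_s <-
      graft$arc[which.min(colSums((t(graft$points) - jp)^2))]
  }
  list(tree = centerline_tree(branches, junctions, spacing),
       truth = list(junctions = lapply(junctions, `[[`, "point"),
                    seed = seed,
                    curvature_amplitude = curvature_amplitude))
}
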