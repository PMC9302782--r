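#' Pulsatile flow waveforms
#'
#' A waveform is a periodic flow signal sampled on a uniform time grid over
#' one cardiac cycle. The grid includes both endpoints (`flow[1] ==
#' flow[n]`), and the cycle time-average (computed over the half-open
#' period, i.e. excluding the duplicated endpoint) equals the requested
#' mean exactly by construction.
#'
#' @param time numeric vector of sample times, s, uniform, from 0 to
#'   `period` inclusive.
#' @param flow numeric vector of flows, m^3/s, same length as `time`,
#'   with `flow[1] == flow[length(flow)]`.
#' @param period cycle duration, s.
#' @param metadata optional list recording how the waveform was generated.
#' @return an object of class `avg_waveform` with elements `time`, `flow`,
#'   `period` and `metadata`.
#' @seealso [make_inlet_waveform()]
#' @export
waveform <- function(time, flow, period, metadata = list()) {
  if (length(time) != length(flow))
    stopf("'time' and 'flow' must have equal length")
  if (length(time) < 3L) stopf("a waveform needs at least 3 samples")
  check_positive(period, "period")
  dt <- diff(time)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stopf("waveform time grid must be uniform")
  if (abs(time[1]) > 1e-12 || abs(time[length(time)] - period) > 1e-9)
    stopf("waveform time grid must span [0, period]")
  if (abs(flow[1] - flow[length(flow)]) >
      1e-9 * max(abs(flow[1]), 1e-30))
    stopf("waveform must be periodic (first and last sample equal)")
  structure(list(time = time, flow = flow, period = period,
                 metadata = metadata),
            class = "avg_waveform")
}

#' @export
print.avg_waveform <- function(x, ...) {
  cat(sprintf(
    "<avg_waveform> period %.3g s, %d samples, mean %.4g mL/min, PI %.3g\n",
    x$period, length(x$time) - 1L,
    m3s_to_mlmin(waveform_mean(x)), pulsatility_index(x$flow[-1L])))
  invisible(x)
}

#' Cycle-average flow of a waveform
#'
#' Time average over one period (trapezoidal rule; for a uniform periodic
#' grid this equals the mean of the samples with the duplicated endpoint
#' dropped), in m^3/s.
#'
#' @param w an `avg_waveform`.
#' @return mean flow, m^3/s.
#' @export
waveform_mean <- function(w) {
  stopifnot(inherits(w, "avg_waveform"))
  mean(w$flow[-length(w$flow)])
}

#' Synthesize a pulsatile inlet waveform
#'
#' Builds a truncated Fourier flow waveform with an exactly enforced cycle
#' mean and pulsatility index. The base morphology is the standard
#' synthetic arterial pulse: a raised-cosine systolic ejection wave
#' (width `systole_width` of the cycle, peaking at `t_peak`) plus a
#' smaller, broader late-diastolic (dicrotic) forward wave, as seen in
#' upper-limb Doppler traces; the sum is band-limited to `harmonics`
#' Fourier terms and rescaled so the cycle mean and pulsatility are exact.
#' A stand-in for a clinical Doppler trace whose published description is
#' limited to its mean. `seed` draws random phase jitter for the
#' harmonics; with the default `phase_jitter = 0` the waveform is the
#' deterministic preset shape and the seed has no effect on it.
#'
#' The preset `"graft_inlet"` uses the postoperative graft flow plus the
#' preoperative brachial flow (990 + 73 = 1063 mL/min) as its mean: the
#' working assumption is that peripheral perfusion is preserved after
#' access creation, so the feeding artery must carry both.
#'
#' @param mean_flow target cycle-mean flow, mL/min.
#' @param pulsatility target pulsatility index (max - min)/mean. Must keep
#'   the minimum flow positive unless `allow_negative = TRUE`.
#' @param period cardiac period, s.
#' @param harmonics number of Fourier harmonics.
#' @param seed integer seed for phase jitter (only used when
#'   `phase_jitter > 0`).
#' @param phase_jitter standard deviation (radians) of random harmonic
#'   phase perturbations.
#' @param n_samples samples per cycle (endpoint duplicated on top).
#' @param t_peak systolic peak time as a fraction of the period.
#' @param systole_width systolic ejection wave width, fraction of the
#'   period.
#' @param dicrotic_amp amplitude of the late-diastolic forward wave
#'   relative to the systolic wave (0 disables it).
#' @param dicrotic_center,dicrotic_width centre and width of the
#'   late-diastolic wave, fractions of the period.
#' @param preset `"graft_inlet"` overrides `mean_flow` with 1063 mL/min.
#' @param allow_negative permit waveforms whose minimum is negative.
#' @return an [waveform()] object; `metadata` records all generator
#'   parameters.
#' @examples
#' w <- make_inlet_waveform(preset = "graft_inlet")
#' m3s_to_mlmin(waveform_mean(w))  # 1063
#' @export
make_inlet_waveform <- function(mean_flow = 990 + 73, pulsatility = 1.5,
                                period = 1.0, harmonics = 5L, seed = NULL,
                                phase_jitter = 0, n_samples = 1000L,
                                t_peak = 0.15, systole_width = 0.3,
                                dicrotic_amp = 0.3, dicrotic_center = 0.55,
                                dicrotic_width = 0.5,
                                preset = c("none", "graft_inlet"),
                                allow_negative = FALSE) {
  preset <- match.arg(preset)
  if (preset == "graft_inlet") mean_flow <- 990 + 73
  check_positive(mean_flow, "mean_flow")
  check_nonnegative(pulsatility, "pulsatility")
  check_positive(period, "period")
  harmonics <- as.integer(harmonics)
  if (harmonics < 1L) stopf("'harmonics' must be >= 1")

  t_open <- seq(0, period, length.out = n_samples + 1L)[seq_len(n_samples)]
  g <- rep(0, n_samples)
  if (pulsatility > 0) {
    hann <- function(center, width) {
      phase <- ((t_open / period - center + width / 2) %% 1) / width
      ifelse(phase >= 0 & phase <= 1, 0.5 * (1 - cos(2 * pi * phase)), 0)
    }
    pulse <- hann(t_peak, systole_width) +
      dicrotic_amp * hann(dicrotic_center, dicrotic_width)
    # band-limit to the requested number of harmonics
    ph <- stats::fft(pulse) / n_samples
    keep <- c(seq_len(harmonics + 1L),
              seq(n_samples - harmonics + 1L, n_samples))
    ph[setdiff(seq_len(n_samples), keep)] <- 0
    if (!is.null(seed) && phase_jitter > 0) {
      jit <- with_seed(seed, stats::rnorm(harmonics, 0, phase_jitter))
      for (k in seq_len(harmonics)) {
        rotk <- exp(1i * jit[k])
        ph[k + 1L] <- ph[k + 1L] * rotk
        ph[n_samples + 1L - k] <- ph[n_samples + 1L - k] * Conj(rotk)
      }
    }
    g <- Re(stats::fft(ph, inverse = TRUE))
    g <- g - mean(g)                     # exact zero mean on the grid
    g <- g * pulsatility / (max(g) - min(g))
  }

  q_mlmin <- mean_flow * (1 + g)
  if (!allow_negative && min(q_mlmin) <= 0)
    stopf("pulsatility %.3g drives the waveform negative (min %.3g mL/min)",
          pulsatility, min(q_mlmin))

  flow <- mlmin_to_m3s(c(q_mlmin, q_mlmin[1L]))
  waveform(c(t_open, period), flow, period,
           metadata = list(mean_flow_mlmin = mean_flow,
                           pulsatility = pulsatility,
                           harmonics = harmonics, seed = seed,
                           phase_jitter = phase_jitter, t_peak = t_peak,
                           systole_width = systole_width,
                           dicrotic_amp = dicrotic_amp,
                           dicrotic_center = dicrotic_center,
                           dicrotic_width = dicrotic_width,
                           preset = preset))
}

#' Read / write waveform CSV files
#'
#' Comma-separated, header row with units in parentheses:
#' `time (s), flow (mL/min)`.
#'
#' @param w an `avg_waveform`.
#' @param path file path.
#' @return `read_waveform_csv` returns an `avg_waveform`;
#'   `write_waveform_csv` returns `path` invisibly.
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "avg_waveform"))
  df <- data.frame(`time (s)` = w$time,
                   `flow (mL/min)` = m3s_to_mlmin(w$flow),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L)
    stopf("waveform CSV '%s' needs time and flow columns", path)
  time <- df[[1L]]
  flow <- mlmin_to_m3s(df[[2L]])
  waveform(time, flow, period = time[length(time)] - time[1L],
           metadata = list(source = path))
}
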