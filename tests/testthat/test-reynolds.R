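test_that("a pure slow trend leaves negligible perturbation RMS", {
  fx <- make_velocity_fixture(profile = 0, n_stations = 5, n_per = 10,
                              n_t = 256, seed = 2)
  rms <- reynolds_rms(fx$series, trend_cutoff = 15)
  expect_lt(max(rms), 0.01 * 0.2)        # < 1% of the trend amplitude
})

test_that("an injected 40 Hz sinusoid is recovered as amp/sqrt(2)", {
  fx <- make_velocity_fixture(profile = 0.1, n_stations = 4, n_per = 10,
                              n_t = 512, perturbation = "sinusoid",
                              perturbation_freq = 40, seed = 3)
  rms <- reynolds_rms(fx$series, trend_cutoff = 15)
  expect_equal(mean(rms), 0.1, tolerance = 0.05)
  expect_equal(rms, fx$truth$target_rms, tolerance = 0.05)
})

test_that("band-limited noise of known RMS is recovered per point", {
  fx <- make_velocity_fixture(profile = c(0.05, 0.1, 0.2), n_per = 40,
                              n_t = 256, perturbation = "band_noise",
                              seed = 4)
  rms <- reynolds_rms(fx$series, trend_cutoff = 15)
  expect_equal(rms, fx$truth$target_rms, tolerance = 0.02)
})

test_that("white-noise perturbations recover sigma on average", {
  set.seed(8)
  n_t <- 512; n_p <- 200; sigma <- 0.07
  t_open <- seq(0, 1, length.out = n_t + 1)[seq_len(n_t)]
  u <- matrix(0.4 + 0.1 * sin(2 * pi * t_open), n_t, n_p) +
    matrix(rnorm(n_t * n_p, 0, sigma), n_t, n_p)
  s <- velocity_field_series(u, 1)
  rms <- reynolds_rms(s, trend_cutoff = 15)
  # the brick-wall filter removes the sub-cutoff noise share:
  # expected RMS^2 = sigma^2 * (1 - n_kept/n)
  n_kept <- sum(pmin(0:(n_t - 1), n_t - 0:(n_t - 1)) <= 15)
  expect_equal(mean(rms), sigma * sqrt(1 - n_kept / n_t),
               tolerance = 0.02)
})

test_that("the trend cutoff must stay below Nyquist", {
  fx <- make_velocity_fixture(profile = 0.1, n_stations = 2, n_per = 5,
                              n_t = 64, perturbation = "sinusoid",
                              perturbation_freq = 20, seed = 1)
  expect_error(reynolds_rms(fx$series, trend_cutoff = 40), "Nyquist")
})

test_that("cross-sectional median profile matches the generator profile", {
  prof <- c(0, 0, 0, 0.25, 0.25, 0.25)    # step at mid-tube
  fx <- make_velocity_fixture(profile = prof, n_per = 30, n_t = 256,
                              tube_length = 100, perturbation = "band_noise",
                              seed = 6)
  rms <- reynolds_rms(fx$series, trend_cutoff = 15)
  branch <- list(points = cbind(seq(0, 100, length.out = 201), 0, 0),
                 arc = seq(0, 100, length.out = 201))
  spacing <- 100 / (length(prof) - 1)
  pr <- cross_sectional_median_profile(rms, fx$series$points, branch,
                                       station_spacing = spacing)
  got <- pr$u_rms_50[seq_along(prof)]
  expect_equal(got[4:6], prof[4:6], tolerance = 0.05)
  expect_lt(max(got[1:3]), 0.0125)       # 5% of the step height
})

test_that("the median is robust to jet-core outliers", {
  rms <- c(1, 2, 100)
  points <- cbind(c(0, 0, 0), c(0, 1, 2), 0)
  branch <- list(points = cbind(c(-1, 0, 1), 0, 0), arc = c(0, 1, 2))
  pr <- cross_sectional_median_profile(rms, points, branch,
                                       station_spacing = 1)
  expect_equal(pr$u_rms_50[pr$n_points == 3], 2)
})

test_that("stations without points are reported missing", {
  rms <- c(0.1, 0.1)
  points <- cbind(c(0, 100), 0, 0)
  branch <- list(points = cbind(seq(0, 100, 1), 0, 0), arc = seq(0, 100, 1))
  pr <- cross_sectional_median_profile(rms, points, branch,
                                       station_spacing = 10)
  expect_true(any(is.na(pr$u_rms_50)))
  expect_true(all(!is.na(pr$u_rms_50[pr$n_points > 0])))
})
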