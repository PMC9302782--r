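test_that("parameter split reproduces the 0.05/0.9/0.05 fractions exactly", {
  p <- split_parameters(100)
  expect_equal(c(p$Z_a, p$R_p, p$Z_v), c(5, 90, 5))
  # components always sum to R_tot exactly
  for (R in c(1e3, 59495886, 7.7e9)) {
    p <- split_parameters(R)
    expect_identical(p$Z_a + p$R_p + p$Z_v, R)
    expect_identical(p$Z_a, p$Z_v)
  }
})

test_that("compliances realise the 0.5 s peripheral time constant", {
  p <- split_parameters(90, tau = 0.5)
  expect_equal(p$C_a, 0.5 / 81)            # tau / (0.9 * R_tot)
  expect_equal(p$R_p * p$C_a, 0.5)
  expect_equal(p$R_p * p$C_v, 0.5)
  p0 <- split_parameters(90, enable_compliance = FALSE)
  expect_identical(p0$C_a, 0)
  expect_identical(p0$C_v, 0)
  expect_error(split_parameters(-1), "positive")
})

test_that("the zero-flow model exchanges no flow for any inputs", {
  bc <- make_zero_flow_bc()
  state <- bc_init_state(bc)
  for (p in list(c(0, 0), c(1e4, -500), c(-2e3, 3e3))) {
    s <- bc_step(bc, state, p[1], p[2], dt = 1e-4)
    expect_identical(s$exchange$q_art_out, 0)
    expect_identical(s$exchange$q_ven_in, 0)
    expect_identical(s$exchange$q_collateral, 0)
  }
})

test_that("zero-compliance ladder equals the series-resistor solution", {
  params <- split_parameters(6e7, enable_compliance = FALSE)
  bc <- make_avc_bc(params)
  state <- bc_init_state(bc)
  dp <- 500
  s <- bc_step(bc, state, dp, 0, dt = 1e-4)
  expect_equal(s$exchange$q_art_out, dp / params$R_tot, tolerance = 1e-12)
  expect_equal(s$exchange$q_ven_in, dp / params$R_tot, tolerance = 1e-12)
  expect_equal(s$exchange$q_micro, dp / params$R_tot, tolerance = 1e-12)
})

test_that("step response follows the two-state RC system's exact solution", {
  params <- split_parameters(6e7)
  bc <- make_avc_bc(params)
  # independent oracle: matrix-exponential solution of
  #   C_a p_Ca' = (dp - p_Ca)/Z_a - (p_Ca - p_Cv)/R_p
  #   C_v p_Cv' = (p_Ca - p_Cv)/R_p - p_Cv/Z_v
  dp <- 1000
  A <- rbind(c(-(1 / params$Z_a + 1 / params$R_p) / params$C_a,
               (1 / params$R_p) / params$C_a),
             c((1 / params$R_p) / params$C_v,
               -(1 / params$R_p + 1 / params$Z_v) / params$C_v))
  b <- c(dp / (params$Z_a * params$C_a), 0)
  x_inf <- solve(A, -b)
  eg <- eigen(A)
  coef <- solve(eg$vectors, -x_inf)      # x(0) = 0
  exact <- function(t)
    Re(x_inf + eg$vectors %*% (coef * exp(eg$values * t)))
  dt <- 1e-5
  state <- bc_init_state(bc)
  for (i in 1:20000) state <- bc_step(bc, state, dp, 0, dt)$state
  ex <- exact(0.2)
  expect_equal(state$p_Ca, ex[1], tolerance = 1e-3)
  expect_equal(state$p_Cv, ex[2], tolerance = 1e-3)
  # terminal flow approaches dp / R_tot
  s <- bc_step(bc, state, dp, 0, dt)
  expect_equal(s$exchange$q_art_out,
               dp / params$R_tot, tolerance = 0.02)
})

test_that("sinusoidal response matches the analytic ladder admittance", {
  params <- fitted_params()
  bc <- make_avc_bc(params)
  P <- 100
  for (f in c(1, 5, 10)) {
    dt <- 2e-4 / f                       # ~5000 steps per period at any f
    n <- round(1 / (f * dt)); ncyc <- 6
    state <- bc_init_state(bc)
    qs <- numeric(n * ncyc); ts <- numeric(n * ncyc)
    for (i in seq_len(n * ncyc)) {
      s <- bc_step(bc, state, P * sin(2 * pi * f * i * dt), 0, dt)
      state <- s$state; qs[i] <- s$exchange$q_art_out; ts[i] <- i * dt
    }
    ix <- (n * (ncyc - 1) + 1):(n * ncyc)
    z <- 2 * mean(qs[ix] * exp(-2i * pi * f * ts[ix]))
    Y <- ladder_admittance(params, f)
    expect_equal(Mod(z), P * Mod(Y), tolerance = 0.005)
    phase_err <- Arg(z / (P * Y * exp(-1i * pi / 2)))
    expect_lt(abs(phase_err) * 180 / pi, 1)
  }
})

test_that("compartment charge is conserved to integrator tolerance", {
  params <- split_parameters(6e7)
  bc <- make_avc_bc(params)
  dt <- 1e-4
  state <- bc_init_state(bc)
  worst <- 0
  for (i in 1:2000) {
    p0 <- c(state$p_Ca, state$p_Cv)
    s <- bc_step(bc, state, 100 * sin(2 * pi * i * dt),
                 10 * cos(2 * pi * 3 * i * dt), dt)
    ex <- s$exchange
    worst <- max(worst,
                 abs(params$C_a * (s$state$p_Ca - p0[1]) -
                       dt * (ex$q_art_out - ex$q_micro)) /
                   max(abs(dt * ex$q_art_out), 1e-300),
                 abs(params$C_v * (s$state$p_Cv - p0[2]) -
                       dt * (ex$q_micro - ex$q_ven_in)) /
                   max(abs(dt * ex$q_micro), 1e-300))
    state <- s$state
  }
  expect_lt(worst, 1e-8)
})

test_that("AVCE with huge collateral resistance reproduces AVC flows", {
  params <- fitted_params()
  avc <- make_avc_bc(params)
  avce <- make_avce_bc(params, R_c_init = 1e20)
  sa <- bc_init_state(avc); se <- bc_init_state(avce)
  for (i in 1:500) {
    pa <- 300 * sin(2 * pi * i * 1e-4); pv <- 20
    ra <- bc_step(avc, sa, pa, pv, 1e-4); sa <- ra$state
    re <- bc_step(avce, se, pa, pv, 1e-4); se <- re$state
  }
  expect_equal(re$exchange$q_art_out, ra$exchange$q_art_out,
               tolerance = 0.01)
  expect_equal(re$exchange$q_ven_in, ra$exchange$q_ven_in,
               tolerance = 0.01)
})

test_that("collateral controller law: fixed point, doubling, clamping", {
  state <- list(R_c = 100, n_freezes = 0L)
  # equal flows leave R_c unchanged
  s <- update_collateral_resistance(state, 1e-5, 1e-5, relaxation = 1)
  expect_identical(s$R_c, 100)
  # q_collateral = 2 q_ven_in with relaxation 1 doubles R_c
  s <- update_collateral_resistance(state, 1e-5, 2e-5, relaxation = 1)
  expect_equal(s$R_c, 200)
  # clamped
  s <- update_collateral_resistance(state, 1e-9, 1e-3, relaxation = 1,
                                    clamp = c(10, 150))
  expect_identical(s$R_c, 150)
  # reversed venous flow freezes the update and is counted
  s <- update_collateral_resistance(state, -1e-6, 1e-5, relaxation = 1)
  expect_identical(s$R_c, 100)
  expect_identical(s$n_freezes, 1L)
})

test_that("constant-pressure harness converges to the even split in < 50 steps", {
  # two parallel resistors from a fixed source pressure: R_fixed (the
  # "vein") and the adjustable R_c; the controller should drive the flows
  # equal, i.e. R_c -> R_fixed
  p_src <- 100; R_fixed <- 50
  state <- list(R_c = 400, n_freezes = 0L)
  for (i in 1:50) {
    q_v <- p_src / R_fixed
    q_c <- p_src / state$R_c
    state <- update_collateral_resistance(state, q_v, q_c,
                                          relaxation = 0.5)
  }
  expect_equal(state$R_c, R_fixed, tolerance = 1e-4)
})

test_that("boundary-parameter JSON round trips with provenance", {
  p <- split_parameters(59495886, tau = 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_bc_params_json(p, path)
  p2 <- read_bc_params_json(path)
  expect_equal(p2$R_tot, p$R_tot)
  expect_equal(p2$C_a, p$C_a)
  expect_equal(p2$Z_v, p$Z_v)
})
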