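test_that("segment impedance follows the Poiseuille and inertance formulas", {
  fl <- fluid_props()                    # 3.5 mPa.s, 1050 kg/m^3
  s <- segment_impedance(0.1, 6e-3, fl)
  expect_equal(s$resistance, 8 * 3.5e-3 * 0.1 / (pi * (3e-3)^4),
               tolerance = 1e-12)
  expect_equal(s$resistance, 1.100e7, tolerance = 1e-3)
  expect_equal(s$inertance, 1050 * 0.1 / (pi * (3e-3)^2), tolerance = 1e-12)
  # linear in length, r^-4 / r^-2 scaling in diameter
  s2 <- segment_impedance(0.2, 6e-3, fl)
  expect_equal(s2$resistance, 2 * s$resistance)
  expect_equal(s2$inertance, 2 * s$inertance)
  s3 <- segment_impedance(0.1, 3e-3, fl)
  expect_equal(s3$resistance, 16 * s$resistance, tolerance = 1e-12)
  expect_error(segment_impedance(-1, 6e-3, fl), "positive")
})

test_that("loop assembly picks up the five geometry segments", {
  loop <- default_loop()
  expect_named(loop$segments, c("proximal_artery", "distal_artery", "graft",
                                "distal_vein", "proximal_vein"))
  lens <- segment_lengths(default_tree())
  for (nm in names(loop$segments))
    expect_equal(loop$segments[[nm]]$length, lens[[nm]] * 1e-3,
                 tolerance = 1e-6)
})

test_that("R_tot fit matches the closed-form parallel divider", {
  # negligible distal/proximal resistances: the inlet flow Q splits
  # between the graft path R_g and the peripheral path R_tot, so
  # R_tot = R_g (Q - q) / q
  R_g <- 1e7
  eps <- 1e-6 * R_g
  Q_ml <- 1000
  loop <- toy_loop(R_da = eps, R_g = R_g, R_dv = eps, R_pv = eps,
                   inlet = make_inlet_waveform(Q_ml, pulsatility = 0))
  for (q_ml in c(100, 250, 500)) {
    R_fit <- as.numeric(fit_total_resistance(loop, q_ml))
    R_expected <- R_g * (Q_ml - q_ml) / q_ml
    expect_equal(R_fit, R_expected, tolerance = 1e-4)
  }
  # symmetric split: target Q/2 recovers R_g itself
  expect_equal(as.numeric(fit_total_resistance(loop, Q_ml / 2)), R_g,
               tolerance = 1e-4)
})

test_that("fitting recovers a known R_tot to 0.1%", {
  loop <- default_loop()
  Q <- waveform_mean(loop$inlet)
  for (R_star in c(1e7, 59495886, 3e8)) {
    q_target <- m3s_to_mlmin(
      avghemo:::steady_solve(loop, Q, R_peri = R_star)$flows[["peripheral"]])
    R_fit <- as.numeric(fit_total_resistance(loop, q_target))
    expect_equal(R_fit, R_star, tolerance = 1e-3)
  }
})

test_that("infeasible fit targets are rejected", {
  loop <- default_loop()
  expect_error(fit_total_resistance(loop, 2000), "infeasible")
})

test_that("fitted loop drives the peripheral mean flow to the target", {
  R_tot <- fit_total_resistance(default_loop(), 73)
  expect_lt(abs(attr(R_tot, "achieved_flow") - 73), 0.1)
})

test_that("zero-flow loop: venous outflow equals arterial inflow pointwise", {
  res <- zf_result()
  expect_equal(res$flows[, "proximal_vein"], res$flows[, "proximal_artery"],
               tolerance = 1e-9)
  expect_equal(max(abs(res$flows[, "distal_artery"])), 0, tolerance = 1e-15)
  expect_equal(max(abs(res$flows[, "distal_vein"])), 0, tolerance = 1e-15)
})

test_that("node mass balance holds to solver precision at every step", {
  for (res in list(zf_result(), avc_result(), avce_result()))
    expect_lt(res$max_balance_residual,
              1e-10 * waveform_mean(default_inlet()))
})

test_that("all default runs reach a periodic regime", {
  expect_true(zf_result()$periodic)
  expect_true(avc_result()$periodic)
  expect_true(avce_result()$periodic)
})

test_that("arteriovenous coupling conserves compartment volume over a cycle", {
  m <- mean_branch_flows(avc_result())
  expect_lt(abs(m[["distal_artery"]] - m[["distal_vein"]]) /
              m[["distal_artery"]], 0.005)
})

test_that("coupling model introduces a venous phase shift absent with zero-flow", {
  period <- 1; dt <- 1e-4
  xcorr_lag <- function(res) {
    spc <- round(period / dt)
    ix <- (nrow(res$flows) - spc + 1):nrow(res$flows)
    a <- res$flows[ix, "proximal_artery"] - mean(res$flows[ix, "proximal_artery"])
    v <- res$flows[ix, "proximal_vein"] - mean(res$flows[ix, "proximal_vein"])
    which.max(sapply(0:200, function(k)
      sum(a * v[(seq_along(v) + k - 1) %% length(v) + 1]))) - 1
  }
  expect_equal(xcorr_lag(zf_result()), 0)
  expect_gt(xcorr_lag(avc_result()), 0)
})

test_that("venous inlet is less pulsatile than the arterial outlet", {
  res <- avc_result()
  expect_lt(pulsatility_index(analysis_flows(res, "distal_vein")),
            pulsatility_index(analysis_flows(res, "distal_artery")))
})

test_that("arterial outlet waveform under coupling is (almost) triphasic", {
  cls <- classify_waveform(analysis_flows(avc_result(), "distal_artery"))
  expect_true(cls %in% c("triphasic", "biphasic"))
  expect_identical(cls, "triphasic")
})

test_that("cycle-mean pressure drop times mean flow is non-negative per segment", {
  res <- avc_result()
  spc <- round(res$period / res$dt)
  ix <- (nrow(res$flows) - spc):nrow(res$flows)
  pr <- res$pressures[ix, ]
  drops <- list(
    distal_artery = pr[, "p_Ja"] - pr[, "p_ao"],
    graft = pr[, "p_Ja"] - pr[, "p_Jv"],
    distal_vein = pr[, "p_vi"] - pr[, "p_Jv"],
    proximal_vein = pr[, "p_Jv"])
  for (nm in names(drops))
    expect_gte(mean(drops[[nm]]) * mean(res$flows[ix, nm]), 0)
})

test_that("AVCE splits the return flow evenly between vein and collaterals", {
  m <- mean_branch_flows(avce_result())
  expect_lt(abs(m[["distal_vein"]] - m[["collateral"]]), 0.1)
})

test_that("constant inlet leads to constant flows with exact node balance", {
  loop <- toy_loop(R_da = 1e6, R_g = 1e7, R_dv = 1e6, R_pv = 5e6,
                   inertance = 1e-3)
  params <- split_parameters(5e7)
  res <- simulate_loop(set_loop_bc(loop, make_avc_bc(params)),
                       n_cycles = 2, dt = 1e-3)
  expect_lt(diff(range(res$flows[, "graft"])),
            1e-9 * mean(res$flows[, "graft"]))
  expect_true(res$periodic)
})

test_that("waveform classification identifies the three canonical shapes", {
  t <- seq(0, 1, length.out = 200)[-200]
  expect_identical(classify_waveform(rep(5, 100)), "monophasic")
  expect_identical(classify_waveform(5 + sin(2 * pi * t)), "monophasic")
  tri <- ifelse(t < 0.25, sin(2 * pi * t / 0.5),
                ifelse(t < 0.45, -0.2 * sin(2 * pi * (t - 0.25) / 0.4), 0.15))
  expect_identical(classify_waveform(tri), "triphasic")
  bi <- ifelse(t < 0.25, sin(2 * pi * t / 0.5), -0.02)
  expect_identical(classify_waveform(bi), "biphasic")
})

test_that("pulsatility index matches hand values and rejects zero mean", {
  t <- seq(0, 1, length.out = 1000)
  expect_equal(pulsatility_index(1 + 0.5 * sin(2 * pi * t)), 1.0,
               tolerance = 1e-5)
  expect_identical(pulsatility_index(rep(3, 10)), 0)
  expect_error(pulsatility_index(sin(2 * pi * t)[-1000] * 0), "zero-mean")
})

test_that("loop result CSV exports flows and pressures in interface units", {
  res <- zf_result()
  path <- withr::local_tempfile(fileext = ".csv")
  write_loop_result_csv(res, path)
  df <- read.csv(path, check.names = FALSE)
  expect_setequal(names(df), c("time (s)", "entity", "value"))
  expect_true(any(grepl("flow:graft", df$entity)))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_exchange_csv(res, path2)
  ex <- read.csv(path2, check.names = FALSE)
  expect_equal(max(abs(ex[["q_art_out (mL/min)"]])), 0, tolerance = 1e-12)
})
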