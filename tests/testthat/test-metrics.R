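random_field <- function(n_points = 60, n_t = 32, seed = 5) {
  set.seed(seed)
  tau <- array(rnorm(n_t * n_points * 3), dim = c(n_t, n_points, 3))
  wss_field_series(tau, areas = runif(n_points, 0.5, 2) * 1e-6, period = 1)
}

test_that("constant, sinusoidal and piecewise fields give closed-form metrics", {
  fx <- make_wss_fixture("constant", amplitude = 5)
  expect_equal(tawss(fx$field), fx$truth$tawss, tolerance = 1e-12)
  expect_equal(wss_max(fx$field), fx$truth$wss_max, tolerance = 1e-12)
  expect_equal(osi(fx$field), fx$truth$osi, tolerance = 1e-12)

  fs <- make_wss_fixture("sinusoid", amplitude = 3, n_t = 256)
  expect_equal(tawss(fs$field), rep(2 * 3 / pi, 200), tolerance = 1e-4)
  expect_equal(wss_max(fs$field), fs$truth$wss_max, tolerance = 1e-3)
  expect_equal(osi(fs$field), rep(0.5, 200), tolerance = 1e-9)

  # half cycle at 2 Pa, half at 4 Pa -> TAWSS 3 Pa
  n_t <- 64; n_p <- 5
  tau <- array(0, dim = c(n_t, n_p, 3))
  tau[, , 1] <- rep(c(2, 4), each = n_t / 2)
  f <- wss_field_series(tau, rep(1e-6, n_p), 1)
  expect_equal(tawss(f), rep(3, n_p))
  expect_equal(wss_max(f), rep(4, n_p))

  # +A for 3T/4, -A for T/4 -> OSI exactly 0.25
  fr <- make_wss_fixture("reversing", amplitude = 2)
  expect_equal(osi(fr$field), rep(0.25, 200), tolerance = 1e-12)
  expect_equal(tawss(fr$field), rep(2, 200), tolerance = 1e-12)
})

test_that("random fields match brute-force per-sample oracles", {
  f <- random_field()
  mag <- sqrt(f$tau[, , 1]^2 + f$tau[, , 2]^2 + f$tau[, , 3]^2)
  # brute force: direct scans over samples
  expect_equal(wss_max(f), apply(mag, 2, max), tolerance = 1e-12)
  expect_equal(tawss(f), apply(mag, 2, mean), tolerance = 1e-12)
  osi_brute <- sapply(seq_len(dim(f$tau)[2]), function(j) {
    mean_vec <- c(mean(f$tau[, j, 1]), mean(f$tau[, j, 2]),
                  mean(f$tau[, j, 3]))
    0.5 * (1 - sqrt(sum(mean_vec^2)) / mean(mag[, j]))
  })
  expect_equal(osi(f), osi_brute, tolerance = 1e-12)
})

test_that("OSI stays in [0, 0.5]; zero for non-reversing fields; NA when undefined", {
  f <- random_field(seed = 9)
  o <- osi(f)
  expect_true(all(o >= 0 & o <= 0.5))
  # unidirectional field with varying magnitude never reverses: OSI 0
  n_t <- 32; n_p <- 10
  tau <- array(0, dim = c(n_t, n_p, 3))
  tau[, , 2] <- outer(1 + 0.5 * sin(2 * pi * seq_len(n_t) / n_t),
                      rep(2, n_p))
  expect_equal(osi(wss_field_series(tau, rep(1e-6, n_p), 1)), rep(0, n_p),
               tolerance = 1e-12)
  # zero shear throughout -> undefined
  tau0 <- array(0, dim = c(n_t, 3, 3))
  expect_true(all(is.na(osi(wss_field_series(tau0, rep(1e-6, 3), 1)))))
})

test_that("metrics are invariant under rigid rotation of all WSS vectors", {
  f <- random_field(seed = 13)
  th <- 0.7
  R3 <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tau_rot <- f$tau
  for (i in seq_len(dim(f$tau)[1]))
    tau_rot[i, , ] <- f$tau[i, , ] %*% t(R3)
  f_rot <- wss_field_series(tau_rot, f$areas, f$period)
  expect_equal(tawss(f_rot), tawss(f), tolerance = 1e-12)
  expect_equal(wss_max(f_rot), wss_max(f), tolerance = 1e-12)
  expect_equal(osi(f_rot), osi(f), tolerance = 1e-12)
})

test_that("halving the time step changes TAWSS and OSI by < 0.5%", {
  mk <- function(n_t) {
    t_open <- seq(0, 1, length.out = n_t + 1)[seq_len(n_t)]
    tau <- array(0, dim = c(n_t, 1, 3))
    tau[, 1, 1] <- 2 + sin(2 * pi * t_open) + 0.3 * cos(4 * pi * t_open)
    tau[, 1, 2] <- 1 + 0.5 * sin(2 * pi * t_open + 1)
    wss_field_series(tau, 1e-6, 1)
  }
  a <- mk(64); b <- mk(128)
  expect_equal(tawss(a), tawss(b), tolerance = 0.005)
  expect_equal(osi(a), osi(b), tolerance = 0.005)
})

test_that("area fractions do exact area bookkeeping", {
  # constructed field: faces holding exactly half the area exceed 7 Pa
  values <- c(10, 10, 1, 1, 1)
  areas <- c(2, 1, 1, 1, 1) * 1e-6
  expect_equal(area_fraction(values, areas, function(x) x > 7), 50)
  expect_equal(area_fraction(values, areas, function(x) x < 0), 0)
  # predicate and complement partition the area
  f <- random_field(seed = 21)
  v <- tawss(f)
  p1 <- area_fraction(v, f$areas, function(x) x > median(v))
  p2 <- area_fraction(v, f$areas, function(x) x <= median(v))
  expect_equal(p1 + p2, 100, tolerance = 1e-9)
  # brute-force oracle on a random field
  thr <- median(v)
  expect_equal(area_fraction(v, f$areas, function(x) x > thr),
               100 * sum(f$areas[v > thr]) / sum(f$areas),
               tolerance = 1e-12)
  expect_error(area_fraction(v, f$areas, function(x) x > 0,
                             mask = list(select = rep(FALSE, length(v)))),
               "empty")
})

test_that("mixed-region fixture reproduces its prescribed high-WSS fraction", {
  fx <- make_wss_fixture("mixed_region", frac_high = 0.3)
  got <- area_fraction(wss_max(fx$field), fx$field$areas,
                       function(x) x > 7)
  expect_equal(got, 30, tolerance = 1e-9)
})

test_that("metric summary reports disjoint bands and undefined-OSI QC", {
  n_t <- 32
  tau <- array(0, dim = c(n_t, 4, 3))
  tau[, 1, 1] <- 0.05          # low
  tau[, 2, 1] <- 20            # high band (7, 40]
  tau[, 3, 1] <- 60            # very high (> 40)
  # point 4: zero shear -> undefined OSI
  f <- wss_field_series(tau, rep(1e-6, 4), 1)
  ms <- metric_summary(f)
  # points 1 (0.05 Pa) and 4 (zero shear, TAWSS 0) are both below 0.1 Pa
  expect_equal(ms$WSS_low, 50)
  expect_equal(ms$WSS_high, 25)
  expect_equal(ms$WSS_very_high, 25)
  expect_identical(attr(ms, "n_undefined_osi"), 1L)
  # boundary: exactly 40 Pa belongs to the high band, not very-high
  tau[, 3, 1] <- 40
  ms2 <- metric_summary(wss_field_series(tau, rep(1e-6, 4), 1))
  expect_equal(ms2$WSS_high, 50)
  expect_equal(ms2$WSS_very_high, 0)
})

test_that("perianastomotic mask selects the stated arc-length window", {
  tree <- default_tree()
  surf <- sweep_and_join(tree)
  m <- perianastomotic_mask(surf, tree)
  s_sel <- surf$vertex_s[m$select] - tree$junctions$venous$host_s
  # window is [-25, +30] mm, closed; the default distal vein is 50 mm and
  # the proximal vein >30 mm, so both bounds are realised
  expect_gte(min(s_sel), -25)
  expect_lte(max(s_sel), 30)
  expect_equal(max(s_sel) - min(s_sel), 55, tolerance = 2)
  expect_true(all(surf$vertex_branch[m$select] == "vein"))
  expect_error(perianastomotic_mask(surf, tree, distal = 0, proximal = 0),
               "empty")
})
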