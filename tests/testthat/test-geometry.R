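test_that("pre-extension branch lengths follow the multiple-times-diameter rule", {
  tree <- build_idealized_centerlines()
  lens <- segment_lengths(tree)
  # vein d = 7.7: proximal 7.5 * 7.7 = 57.75, distal 3.25 * 7.7 = 25.025
  expect_equal(lens[["proximal_vein"]], 57.75, tolerance = 1e-6)
  expect_equal(lens[["distal_vein"]], 25.025, tolerance = 1e-6)
  # artery d = 6.6: proximal 49.5, distal 21.45
  expect_equal(lens[["proximal_artery"]], 49.5, tolerance = 1e-6)
  expect_equal(lens[["distal_artery"]], 21.45, tolerance = 1e-6)
})

test_that("flow extensions double every host segment to 2 x multiple x diameter", {
  tree <- trim_and_extend(build_idealized_centerlines())
  lens <- segment_lengths(tree)
  expect_equal(lens[["proximal_vein"]], 115.5, tolerance = 0.1)   # 2*7.5*7.7
  expect_equal(lens[["distal_vein"]], 50.05, tolerance = 0.1)     # 2*3.25*7.7
  expect_equal(lens[["proximal_artery"]], 99.0, tolerance = 0.1)  # 2*7.5*6.6
  expect_equal(lens[["distal_artery"]], 42.9, tolerance = 0.1)    # 2*3.25*6.6
})

test_that("trim_and_extend is idempotent", {
  t1 <- trim_and_extend(build_idealized_centerlines())
  t2 <- trim_and_extend(t1)
  expect_equal(segment_lengths(t2), segment_lengths(t1), tolerance = 1e-6)
  for (nm in names(t1$branches))
    expect_equal(t2$branches[[nm]]$points, t1$branches[[nm]]$points,
                 tolerance = 1e-6)
})

test_that("trim errors when a branch is shorter than the requested trim", {
  tree <- build_idealized_centerlines()
  fat <- list(artery = vessel_spec("artery", 6.6, proximal_multiple = 50),
              vein = vessel_spec("vein", 7.7),
              graft = vessel_spec("graft", 6))
  expect_error(trim_and_extend(tree, fat), "shorter than")
})

test_that("zero multiples collapse a branch to its anastomosis point", {
  tree <- build_idealized_centerlines()
  degenerate <- list(
    artery = vessel_spec("artery", 6.6, proximal_multiple = 0,
                         distal_multiple = 0),
    vein = vessel_spec("vein", 7.7), graft = vessel_spec("graft", 6))
  expect_error(trim_and_extend(tree, degenerate), "zero length")
})

test_that("anastomotic angles round-trip through build and measurement", {
  for (th in c(30, 45, 60, 90)) {
    an <- list(arterial = anastomosis_spec(th), venous = anastomosis_spec(th))
    tr <- build_idealized_centerlines(anastomoses = an)
    expect_equal(measure_anastomosis_angle(tr, "arterial"), th,
                 tolerance = 0.5 / th)
    expect_equal(measure_anastomosis_angle(tr, "venous"), th,
                 tolerance = 0.5 / th)
  }
})

test_that("angles survive trimming and extension", {
  tr <- default_tree()
  expect_equal(measure_anastomosis_angle(tr, "arterial"), 45,
               tolerance = 0.5 / 45)
  expect_equal(measure_anastomosis_angle(tr, "venous"), 45,
               tolerance = 0.5 / 45)
})

test_that("a 90-degree build leaves the graft perpendicular to the vein", {
  an <- list(arterial = anastomosis_spec(90), venous = anastomosis_spec(90))
  tr <- build_idealized_centerlines(anastomoses = an)
  g <- tr$branches$graft$points
  v_axis <- c(1, 0, 0)
  t_end <- g[nrow(g), ] - g[nrow(g) - 4L, ]
  expect_lt(abs(sum(t_end * v_axis) / sqrt(sum(t_end^2))), 0.02)
})

test_that("nearly collinear graft-host junction is flagged", {
  tree <- build_idealized_centerlines()
  # forge a graft that runs along the artery axis
  n <- 50
  tree$branches$graft$points <- cbind(seq(0, 40, length.out = n), 0, 0)
  tree$branches$graft$arc <- seq(0, 40, length.out = n)
  tree$branches$graft$radius <- rep(3, n)
  expect_warning(measure_anastomosis_angle(tree, "arterial"), "collinear")
})

test_that("invalid specs are rejected", {
  expect_error(anastomosis_spec(0), "between 0 and 180")
  expect_error(anastomosis_spec(180), "between 0 and 180")
  expect_error(vessel_spec("artery", -1), "positive")
  expect_error(build_idealized_centerlines(
    graft_path = list(loop_width = 0, venous_offset = 0)),
    "coincide")
})
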