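#' Blood rheology for the surrogate network
#'
#' Newtonian blood: dynamic viscosity 3.5 mPa.s and density 1050 kg/m^3 by
#' default (standard literature values for blood at high shear).
#'
#' @param dynamic_viscosity Pa.s.
#' @param density kg/m^3.
#' @return object of class `avg_fluid_props`.
#' @export
fluid_props <- function(dynamic_viscosity = 3.5e-3, density = 1050) {
  check_positive(dynamic_viscosity, "dynamic_viscosity")
  check_positive(density, "density")
  structure(list(dynamic_viscosity = dynamic_viscosity, density = density),
            class = "avg_fluid_props")
}

#' Poiseuille impedance of a vessel segment
#'
#' Lumps a straight vessel segment into a resistance `R = 8 mu L /
#' (pi r^4)` and an inertance `Lin = rho L / (pi r^2)`; together these
#' are the surrogate for the distributed 3D flow domain.
#'
#' @param length segment length, m.
#' @param diameter lumen diameter, m.
#' @param fluid an [fluid_props()].
#' @param label segment name.
#' @return object of class `avg_network_segment` with `resistance`
#'   (Pa.s/m^3) and `inertance` (Pa.s^2/m^3).
#' @export
segment_impedance <- function(length, diameter, fluid = fluid_props(),
                              label = "segment") {
  check_positive(length, "length")
  check_positive(diameter, "diameter")
  r <- diameter / 2
  structure(list(label = label,
                 resistance = 8 * fluid$dynamic_viscosity * length / (pi * r^4),
                 inertance = fluid$density * length / (pi * r^2),
                 length = length, diameter = diameter),
            class = "avg_network_segment")
}

#' @export
print.avg_network_segment <- function(x, ...) {
  cat(sprintf("<avg_network_segment> %s: R %.4g Pa.s/m^3, L %.4g Pa.s^2/m^3\n",
              x$label, x$resistance, x$inertance))
  invisible(x)
}

SEGMENT_NAMES <- c("proximal_artery", "distal_artery", "graft",
                   "distal_vein", "proximal_vein")

#' Assemble the graft-circuit flow loop
#'
#' Builds the lumped surrogate of the full inlet-to-outlet loop: five
#' resistance-inertance segments (proximal/distal artery, graft,
#' distal/proximal vein) whose lengths and diameters are read off a
#' centerline tree, a prescribed pulsatile inlet flow, a fixed venous
#' outlet pressure (0 mmHg by default -- only pressure differences matter
#' in a rigid loop), and a distal boundary model attached at the arterial
#' outlet and venous inlet nodes.
#'
#' `loop_model()` is the lower-level constructor taking explicit segments
#' (used for toy networks in tests).
#'
#' @param geometry an [centerline_tree()] with both junctions.
#' @param fluid an [fluid_props()].
#' @param bc an `avg_bc_model`.
#' @param inlet an [waveform()] (arterial inlet flow).
#' @param p_out venous outlet pressure, Pa.
#' @return object of class `avg_loop_model`.
#' @export
assemble_loop <- function(geometry, fluid = fluid_props(),
                          bc = make_zero_flow_bc(), inlet, p_out = 0) {
  lens <- segment_lengths(geometry)
  dia <- c(proximal_artery = 2 * geometry$branches$artery$radius[1],
           distal_artery = 2 * geometry$branches$artery$radius[1],
           graft = 2 * geometry$branches$graft$radius[1],
           distal_vein = 2 * geometry$branches$vein$radius[1],
           proximal_vein = 2 * geometry$branches$vein$radius[1])
  segs <- lapply(SEGMENT_NAMES, function(nm) {
    if (lens[[nm]] <= 0) stopf("geometry missing segment '%s'", nm)
    segment_impedance(mm_to_m(lens[[nm]]), mm_to_m(dia[[nm]]), fluid,
                      label = nm)
  })
  loop_model(stats::setNames(segs, SEGMENT_NAMES), bc, inlet, p_out)
}

#' @param segments named list of five [segment_impedance()] objects
#'   (`proximal_artery`, `distal_artery`, `graft`, `distal_vein`,
#'   `proximal_vein`).
#' @rdname assemble_loop
#' @export
loop_model <- function(segments, bc = make_zero_flow_bc(), inlet,
                       p_out = 0) {
  missing <- setdiff(SEGMENT_NAMES, names(segments))
  if (length(missing))
    stopf("missing segments: %s", paste(missing, collapse = ", "))
  if (!inherits(bc, "avg_bc_model")) stopf("'bc' must be an avg_bc_model")
  if (!inherits(inlet, "avg_waveform"))
    stopf("'inlet' must be an avg_waveform")
  structure(list(segments = segments[SEGMENT_NAMES], bc = bc,
                 inlet = inlet, p_out = p_out),
            class = "avg_loop_model")
}

#' @export
print.avg_loop_model <- function(x, ...) {
  cat(sprintf("<avg_loop_model> bc %s, inlet mean %.4g mL/min\n",
              x$bc$kind, m3s_to_mlmin(waveform_mean(x$inlet))))
  invisible(x)
}

#' Swap the boundary model of a loop
#'
#' @param loop an `avg_loop_model`.
#' @param bc replacement `avg_bc_model`.
#' @return the loop with `bc` attached.
#' @export
set_loop_bc <- function(loop, bc) {
  stopifnot(inherits(loop, "avg_loop_model"),
            inherits(bc, "avg_bc_model"))
  loop$bc <- bc
  loop
}

# Steady resistive solve of the loop with a series peripheral resistance
# R_peri between the arterial-outlet and venous-inlet nodes (Inf = no
# peripheral path). Returns node pressures and branch flows.
steady_solve <- function(loop, Q, R_peri = Inf) {
  R <- vapply(loop$segments, `[[`, numeric(1), "resistance")
  g_da <- 1 / R[["distal_artery"]]; g_g <- 1 / R[["graft"]]
  g_dv <- 1 / R[["distal_vein"]]; g_pv <- 1 / R[["proximal_vein"]]
  g_t <- if (is.finite(R_peri)) 1 / R_peri else 0
  p_out <- loop$p_out
  # unknowns: p_Ja, p_Jv, p_ao, p_vi
  A <- rbind(
    c(g_da + g_g, -g_g, -g_da, 0),
    c(g_g, -(g_g + g_dv + g_pv), 0, g_dv),
    c(g_da, 0, -(g_da + g_t), g_t),
    c(0, g_dv, g_t, -(g_t + g_dv)))
  b <- c(Q, -g_pv * p_out, 0, 0)
  p <- solve(A, b)
  names(p) <- c("p_Ja", "p_Jv", "p_ao", "p_vi")
  q_peri <- g_t * (p[["p_ao"]] - p[["p_vi"]])
  list(pressures = p,
       flows = c(proximal_artery = Q,
                 distal_artery = g_da * (p[["p_Ja"]] - p[["p_ao"]]),
                 graft = g_g * (p[["p_Ja"]] - p[["p_Jv"]]),
                 distal_vein = g_dv * (p[["p_vi"]] - p[["p_Jv"]]),
                 proximal_vein = g_pv * (p[["p_Jv"]] - p_out),
                 peripheral = q_peri),
       p_inlet = p[["p_Ja"]] + Q * R[["proximal_artery"]])
}

# Frequency-domain periodic solution of the (LTI) loop + coupling-model
# system, used to initialise time stepping at the periodic orbit. For each
# retained harmonic of the inlet flow the 6-unknown complex nodal system
# (4 domain nodes + 2 compartment pressures) is solved; R_c is held at its
# initial value. Returns the t = 0 segment flows, node pressures,
# compartment pressures and the DC venous/collateral flows.
periodic_loop_init <- function(loop, q_in_cycle, period, R_c = Inf) {
  stopifnot(!inherits(loop$bc, "avg_bc_zero"))
  pr <- loop$bc$params
  R <- vapply(loop$segments, `[[`, numeric(1), "resistance")
  L <- vapply(loop$segments, `[[`, numeric(1), "inertance")
  N <- length(q_in_cycle)
  Qh <- stats::fft(q_in_cycle) / N
  keep <- which(Mod(Qh) > 1e-12 * max(Mod(Qh)))
  yc <- if (is.finite(R_c)) 1 / R_c else 0

  acc <- rep(0 + 0i, 6)
  q_acc <- rep(0 + 0i, 4)       # distal_artery, graft, distal_vein, proximal_vein
  dc <- NULL
  for (k in keep) {
    k_signed <- if (k - 1L <= N / 2) k - 1L else k - 1L - N
    w <- 2 * pi * k_signed / period
    y_da <- 1 / (R[["distal_artery"]] + 1i * w * L[["distal_artery"]])
    y_g <- 1 / (R[["graft"]] + 1i * w * L[["graft"]])
    y_dv <- 1 / (R[["distal_vein"]] + 1i * w * L[["distal_vein"]])
    y_pv <- 1 / (R[["proximal_vein"]] + 1i * w * L[["proximal_vein"]])
    ya <- 1 / pr$Z_a; yv <- 1 / pr$Z_v; yp <- 1 / pr$R_p
    A <- rbind(
      c(y_da + y_g, -y_g, -y_da, 0, 0, 0),
      c(y_g, -(y_g + y_dv + y_pv), 0, y_dv, 0, 0),
      c(y_da, 0, -(y_da + ya), 0, ya, 0),
      c(0, y_dv, 0, -(y_dv + yv), 0, yv),
      c(0, 0, ya, 0, -(ya + yp + 1i * w * pr$C_a), yp),
      c(0, 0, 0, yv, yp, -(yp + yv + yc + 1i * w * pr$C_v)))
    b <- c(Qh[k], 0, 0, 0, 0, 0)
    x <- solve(A, b)
    acc <- acc + x
    q_acc <- q_acc + c(y_da * (x[1] - x[3]), y_g * (x[1] - x[2]),
                       y_dv * (x[4] - x[2]), y_pv * x[2])
    if (k_signed == 0L)
      dc <- list(q_ven = Re(yv * (x[6] - x[4])), q_col = Re(yc * x[6]))
  }
  # the solve references the outlet (and collateral return) at 0; a
  # nonzero outlet pressure is a uniform DC shift of every pressure
  list(p = Re(acc[1:4]) + loop$p_out,
       q = c(proximal_artery = Re(sum(Qh[keep])),
             distal_artery = Re(q_acc[1]), graft = Re(q_acc[2]),
             distal_vein = Re(q_acc[3]), proximal_vein = Re(q_acc[4])),
       p_Ca = Re(acc[5]) + loop$p_out, p_Cv = Re(acc[6]) + loop$p_out,
       dc = dc)
}

# DC even-split collateral resistance: root-find R_c so the steady
# venous-inlet and collateral flows are equal.
dc_even_split_rc <- function(loop, Q_mean) {
  f <- function(logR) {
    init <- periodic_loop_init(loop, Q_mean, period = 1, R_c = 10^logR)
    init$dc$q_ven - init$dc$q_col
  }
  path_R <- loop$bc$params$Z_v +
    loop$segments$distal_vein$resistance +
    loop$segments$proximal_vein$resistance
  bracket <- log10(path_R) + c(-3, 3)
  if (sign(f(bracket[1])) == sign(f(bracket[2])))
    stopf("could not bracket the even-split collateral resistance")
  10^stats::uniroot(f, bracket, tol = 1e-10)$root
}

#' Fit the total peripheral resistance
#'
#' Reproduces the calibration procedure for the arteriovenous coupling
#' models: with all compliances set to zero the peripheral ladder is a
#' pure series resistance `R_tot = Z_a + R_p + Z_v`; the cycle-mean inlet
#' flow is prescribed and `R_tot` is adjusted by a bracketing root-finder
#' on `log10(R_tot)` until the steady flow through the peripheral branch
#' matches the target (the preoperatively measured flow that should keep
#' perfusing the periphery after access creation).
#'
#' @param loop an `avg_loop_model`.
#' @param target_flow target peripheral mean flow, mL/min.
#' @param tol fit tolerance on the peripheral flow, mL/min.
#' @param bracket log10 search interval for `R_tot`, Pa.s/m^3.
#' @return fitted `R_tot` (Pa.s/m^3) with attribute `achieved_flow`
#'   (mL/min).
#' @examples
#' tree <- trim_and_extend(build_idealized_centerlines())
#' loop <- assemble_loop(tree, inlet = make_inlet_waveform(preset = "graft_inlet"))
#' R_tot <- fit_total_resistance(loop, 73)
#' @export
fit_total_resistance <- function(loop, target_flow, tol = 0.1,
                                 bracket = c(2, 15)) {
  check_positive(target_flow, "target_flow")
  Q <- waveform_mean(loop$inlet)
  target <- mlmin_to_m3s(target_flow)
  if (target >= Q)
    stopf("infeasible target: peripheral flow %.3g mL/min >= inlet mean %.3g mL/min",
          target_flow, m3s_to_mlmin(Q))
  f <- function(logR)
    steady_solve(loop, Q, R_peri = 10^logR)$flows[["peripheral"]] - target
  lo <- f(bracket[1]); hi <- f(bracket[2])
  if (sign(lo) == sign(hi))
    stopf("bracket [1e%g, 1e%g] does not enclose the target flow",
          bracket[1], bracket[2])
  root <- stats::uniroot(f, bracket, tol = 1e-12)
  R_tot <- 10^root$root
  achieved <- m3s_to_mlmin(
    steady_solve(loop, Q, R_peri = R_tot)$flows[["peripheral"]])
  if (abs(achieved - target_flow) > tol)
    stopf("fit did not converge: achieved %.4f, target %.4f mL/min",
          achieved, target_flow)
  structure(R_tot, achieved_flow = achieved)
}
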