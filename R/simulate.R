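#' Simulate the graft flow loop
#'
#' Semi-implicit time integration of the resistance-inertance loop
#' coupled to the distal boundary model through the pressure-in/flow-out
#' stepping contract. Segment flows are advanced by backward differences
#' (`q^{n+1} = (L/dt q^n + dp) / (R + L/dt)`), the boundary impedance
#' admittances are embedded in the nodal system, and the compartment
#' pressures are relaxed by a fixed number of sub-iterations per step
#' (their per-step coupling gain is tiny when compliances are enabled, so
#' two sub-iterations suffice). Because the loop plus coupling model is a
#' linear time-invariant system, the run is initialised at its periodic
#' orbit (frequency-domain solve per inlet harmonic); the slow peripheral
#' charging mode (time constant `R_p C` = 0.5 s) therefore carries no
#' start-up transient and the standard three-cycle protocol, with the last
#' cycle as the analysis cycle, is already periodic.
#'
#' For the collateral-extended boundary model the collateral resistance is
#' re-tuned before every step by [update_collateral_resistance()], driven
#' by exponentially smoothed venous/collateral flows (see
#' [make_avce_bc()]); if no initial value was configured it starts at the
#' steady-state even-split value found by root-finding.
#'
#' @param loop an `avg_loop_model`.
#' @param n_cycles cycles to simulate.
#' @param dt time step, s (must divide the cycle period).
#' @param sub_iter coupling sub-iterations per step.
#' @return object of class `avg_loop_result`: `time` (s), `flows` (step x
#'   branch matrix, m^3/s, branches `proximal_artery`, `distal_artery`,
#'   `graft`, `distal_vein`, `proximal_vein`, `collateral`), `pressures`
#'   (step x node, Pa), `bc_trace` (compartment pressures and `R_c`),
#'   `period`, `n_cycles`, `analysis_cycle`, `max_balance_residual`,
#'   `periodic` flag and `n_freezes`.
#' @export
simulate_loop <- function(loop, n_cycles = 3, dt = 1e-4, sub_iter = 2L) {
  stopifnot(inherits(loop, "avg_loop_model"))
  check_positive(dt, "dt")
  period <- loop$inlet$period
  steps_per_cycle <- round(period / dt)
  if (abs(steps_per_cycle * dt - period) > 1e-9 * period)
    stopf("dt = %g does not divide the period %g", dt, period)
  n_steps <- steps_per_cycle * n_cycles

  R <- vapply(loop$segments, `[[`, numeric(1), "resistance")
  L <- vapply(loop$segments, `[[`, numeric(1), "inertance")
  # discrete segment law: q' = beta q + G dp
  G <- 1 / (R + L / dt)
  beta <- (L / dt) * G
  g_da <- G[["distal_artery"]]; g_g <- G[["graft"]]
  g_dv <- G[["distal_vein"]]; g_pv <- G[["proximal_vein"]]
  b_da <- beta[["distal_artery"]]; b_g <- beta[["graft"]]
  b_dv <- beta[["distal_vein"]]; b_pv <- beta[["proximal_vein"]]
  p_out <- loop$p_out

  bc <- loop$bc
  y <- bc_conductances(bc)
  # nodal unknowns: p_Ja, p_Jv, p_ao, p_vi
  A <- rbind(
    c(g_da + g_g, -g_g, -g_da, 0),
    c(g_g, -(g_g + g_dv + g_pv), 0, g_dv),
    c(g_da, 0, -(g_da + y$y_art), 0),
    c(0, g_dv, 0, -(g_dv + y$y_ven)))
  Ainv <- solve(A)

  # inlet flow sampled at step times (cyclic linear interpolation)
  t_all <- seq(0, n_steps) * dt
  q_in <- stats::approx(loop$inlet$time, loop$inlet$flow,
                        xout = t_all %% period, rule = 2)$y

  # initialise at the periodic orbit of the LTI system (frequency-domain
  # solve per inlet harmonic) so the 3-cycle protocol starts converged;
  # the zero-flow model carries no state and starts from its steady solve
  Q_mean <- waveform_mean(loop$inlet)
  is_avc_like <- !inherits(bc, "avg_bc_zero")
  state <- bc_init_state(bc)
  relax_step <- NULL; clamp <- NULL
  buf_ven <- NULL; buf_col <- NULL; sum_ven <- 0; sum_col <- 0
  if (!is_avc_like) {
    ss <- steady_solve(loop, Q_mean, Inf)
    q <- ss$flows[SEGMENT_NAMES]
    p <- unname(ss$pressures)
  } else {
    if (inherits(bc, "avg_bc_avce") && !is.finite(state$R_c))
      state$R_c <- dc_even_split_rc(loop, Q_mean)
    R_c0 <- if (inherits(bc, "avg_bc_avce")) state$R_c else Inf
    init <- periodic_loop_init(loop, q_in[seq_len(steps_per_cycle)],
                               period, R_c = R_c0)
    q <- init$q
    p <- init$p
    state$p_Ca <- init$p_Ca
    state$p_Cv <- init$p_Cv
    if (inherits(bc, "avg_bc_avce")) {
      relax_step <- min(1, bc$relaxation * dt / bc$ctrl_timescale)
      clamp <- state$R_c * c(1 / bc$clamp_factor, bc$clamp_factor)
      # one-cycle running-mean buffers, seeded with the DC (cycle-mean)
      # flows of the periodic initial state
      buf_ven <- rep(init$dc$q_ven, steps_per_cycle)
      buf_col <- rep(init$dc$q_col, steps_per_cycle)
      sum_ven <- sum(buf_ven); sum_col <- sum(buf_col)
    }
  }

  flows <- matrix(NA_real_, n_steps + 1L, 6,
                  dimnames = list(NULL, c(SEGMENT_NAMES, "collateral")))
  pressures <- matrix(NA_real_, n_steps + 1L, 4,
                      dimnames = list(NULL, c("p_Ja", "p_Jv", "p_ao", "p_vi")))
  bc_trace <- matrix(NA_real_, n_steps + 1L, 3,
                     dimnames = list(NULL, c("p_Ca", "p_Cv", "R_c")))
  flows[1L, ] <- c(q, 0)
  pressures[1L, ] <- p
  bc_trace[1L, ] <- c(state$p_Ca, state$p_Cv, state$R_c)

  max_resid <- 0
  inlet_scale <- max(abs(Q_mean), 1e-30)
  for (n in seq_len(n_steps)) {
    Qn <- q_in[n + 1L]
    # the controller engages once a full cycle of flow history exists
    # (before that the running means still mix in the seed values and
    # carry uncancelled harmonics)
    if (inherits(bc, "avg_bc_avce") && n > steps_per_cycle)
      state <- update_collateral_resistance(state, sum_ven / steps_per_cycle,
                                            sum_col / steps_per_cycle,
                                            relax_step, clamp)
    p_Ca_star <- state$p_Ca; p_Cv_star <- state$p_Cv
    trial <- NULL
    for (it in seq_len(sub_iter)) {
      b <- c(Qn - b_da * q[["distal_artery"]] - b_g * q[["graft"]],
             -g_pv * p_out - b_g * q[["graft"]] - b_dv * q[["distal_vein"]] +
               b_pv * q[["proximal_vein"]],
             -b_da * q[["distal_artery"]] - y$y_art * p_Ca_star,
             b_dv * q[["distal_vein"]] - y$y_ven * p_Cv_star)
      p <- drop(Ainv %*% b)
      trial <- bc_step(bc, state, p[3L], p[4L], dt, p_ven_out = p_out)
      p_Ca_star <- trial$state$p_Ca
      p_Cv_star <- trial$state$p_Cv
    }
    state <- trial$state
    q_new <- c(
      proximal_artery = Qn,
      distal_artery = b_da * q[["distal_artery"]] + g_da * (p[1L] - p[3L]),
      graft = b_g * q[["graft"]] + g_g * (p[1L] - p[2L]),
      distal_vein = b_dv * q[["distal_vein"]] + g_dv * (p[4L] - p[2L]),
      proximal_vein = b_pv * q[["proximal_vein"]] + g_pv * (p[2L] - p_out))
    resid <- max(abs(Qn - q_new[["distal_artery"]] - q_new[["graft"]]),
                 abs(q_new[["graft"]] + q_new[["distal_vein"]] -
                       q_new[["proximal_vein"]]))
    max_resid <- max(max_resid, resid)
    if (max(abs(q_new)) > 1e3 * inlet_scale)
      stopf("simulation diverged at t = %.4f s", n * dt)
    q <- q_new
    if (inherits(bc, "avg_bc_avce")) {
      slot <- (n - 1L) %% steps_per_cycle + 1L
      sum_ven <- sum_ven - buf_ven[slot] + trial$exchange$q_ven_in
      sum_col <- sum_col - buf_col[slot] + trial$exchange$q_collateral
      buf_ven[slot] <- trial$exchange$q_ven_in
      buf_col[slot] <- trial$exchange$q_collateral
    }
    flows[n + 1L, ] <- c(q, trial$exchange$q_collateral)
    pressures[n + 1L, ] <- p
    bc_trace[n + 1L, ] <- c(state$p_Ca, state$p_Cv, state$R_c)
  }

  # periodicity: RMS difference between the last two cycles per branch
  periodic <- TRUE
  if (n_cycles >= 2L) {
    i3 <- (n_steps - steps_per_cycle + 1L):n_steps + 1L
    i2 <- i3 - steps_per_cycle
    for (k in seq_len(ncol(flows))) {
      scale <- max(sqrt(mean(flows[i3, k]^2)), 1e-12 * inlet_scale)
      if (sqrt(mean((flows[i3, k] - flows[i2, k])^2)) / scale > 0.01)
        periodic <- FALSE
    }
    if (!periodic)
      warning("last two cycles differ by > 1% RMS; result not periodic")
  }

  structure(list(time = t_all, flows = flows, pressures = pressures,
                 bc_trace = bc_trace, period = period, dt = dt,
                 n_cycles = n_cycles, analysis_cycle = n_cycles,
                 max_balance_residual = max_resid, periodic = periodic,
                 n_freezes = state$n_freezes),
            class = "avg_loop_result")
}

#' @export
print.avg_loop_result <- function(x, ...) {
  cat(sprintf(
    "<avg_loop_result> %d cycles @ dt %.2g s, periodic: %s\n",
    x$n_cycles, x$dt, x$periodic))
  m <- mean_branch_flows(x)
  for (nm in names(m)) cat(sprintf("  %-16s %9.2f mL/min\n", nm, m[[nm]]))
  invisible(x)
}

cycle_indices <- function(result, cycle) {
  if (cycle < 1 || cycle > result$n_cycles)
    stopf("cycle index %d out of range [1, %d]", cycle, result$n_cycles)
  spc <- round(result$period / result$dt)
  ((cycle - 1L) * spc):(cycle * spc) + 1L    # inclusive of both endpoints
}

#' Cycle-mean branch flows
#'
#' Trapezoidal time average of every branch flow over one cycle of a
#' simulation, in mL/min.
#'
#' @param result an `avg_loop_result`.
#' @param cycle cycle index (defaults to the analysis cycle).
#' @return named numeric vector, mL/min.
#' @export
mean_branch_flows <- function(result, cycle = result$analysis_cycle) {
  ix <- cycle_indices(result, cycle)
  m <- apply(result$flows[ix, , drop = FALSE], 2L, trapz_mean)
  m3s_to_mlmin(m)
}

# mean of a uniformly sampled series by the trapezoidal rule (first and
# last samples half-weighted)
trapz_mean <- function(x) {
  n <- length(x)
  (sum(x) - (x[1] + x[n]) / 2) / (n - 1)
}

#' Pulsatility index of a flow series
#'
#' `(max - min) / mean` over one cycle.
#'
#' @param flow numeric flow series (one cycle).
#' @return dimensionless PI.
#' @export
pulsatility_index <- function(flow) {
  m <- mean(flow)
  if (abs(m) < 1e-300) stopf("pulsatility index undefined for zero-mean flow")
  (max(flow) - min(flow)) / m
}

#' Classify a periodic flow waveform
#'
#' Doppler-style phase segmentation of an arterial flow trace over one
#' cycle: a systolic antegrade peak, an early-diastolic
#' retrograde-or-near-zero dip (at or below `dip_threshold` of the peak),
#' and a distinct later antegrade phase (recovering to at least
#' `antegrade_threshold` of the peak before the upstroke into the next
#' systole) classify the trace as `triphasic`. A trace whose dip never
#' recovers is `biphasic`; a single-signed trace without a qualifying dip
#' is `monophasic`. The trailing strictly monotone rise of the (rotated)
#' cycle is excluded as the next systole's upstroke.
#'
#' @param flow numeric flow series over one cycle (treated as periodic).
#' @param dip_threshold dip level as a fraction of the systolic peak.
#' @param antegrade_threshold late-recovery level as a fraction of the
#'   peak.
#' @return one of `"monophasic"`, `"biphasic"`, `"triphasic"`.
#' @export
classify_waveform <- function(flow, dip_threshold = 0.05,
                              antegrade_threshold = 0.1) {
  n <- length(flow)
  if (n < 4L) stopf("need a full cycle of samples")
  qmax <- max(flow)
  if (qmax <= 0) stopf("waveform has no antegrade phase")
  # rotate so the systolic peak leads
  rot <- c(which.max(flow):n, seq_len(which.max(flow) - 1L))
  f <- flow[rot]
  idip <- which.min(f)
  if (f[idip] > dip_threshold * qmax) return("monophasic")
  # exclude the upstroke into the next systole (trailing strict rise)
  m <- n
  while (m > 1L && f[m] > f[m - 1L]) m <- m - 1L
  late <- if (idip < m) max(f[(idip + 1L):m]) else -Inf
  if (late >= antegrade_threshold * qmax) "triphasic" else "biphasic"
}

#' Export a loop simulation as CSV
#'
#' Long format `time (s), entity, value`; flows in mL/min, pressures in
#' mmHg.
#'
#' @param result an `avg_loop_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_loop_result_csv <- function(result, path) {
  n <- length(result$time)
  ent_f <- colnames(result$flows); ent_p <- colnames(result$pressures)
  df <- rbind(
    data.frame(`time (s)` = rep(result$time, length(ent_f)),
               entity = rep(paste0("flow:", ent_f), each = n),
               value = m3s_to_mlmin(as.vector(result$flows)),
               check.names = FALSE),
    data.frame(`time (s)` = rep(result$time, length(ent_p)),
               entity = rep(paste0("pressure:", ent_p), each = n),
               value = pa_to_mmhg(as.vector(result$pressures)),
               check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export boundary exchange-flow series as CSV
#'
#' Columns `t (s), q_art_out (mL/min), q_ven_in (mL/min),
#' q_collateral (mL/min)` -- the table an external solver would consume as
#' a boundary condition.
#'
#' @param result an `avg_loop_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_exchange_csv <- function(result, path) {
  df <- data.frame(`t (s)` = result$time,
                   `q_art_out (mL/min)` =
                     m3s_to_mlmin(result$flows[, "distal_artery"]),
                   `q_ven_in (mL/min)` =
                     m3s_to_mlmin(result$flows[, "distal_vein"]),
                   `q_collateral (mL/min)` =
                     m3s_to_mlmin(result$flows[, "collateral"]),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
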