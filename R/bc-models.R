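#' Lumped distal boundary-condition parameters
#'
#' Splits a fitted total peripheral resistance into the elements of the
#' arteriovenous coupling ladder: characteristic impedances coupling the
#' flow domain to the compartments (`Z_a = Z_v = 0.05 R_tot`), the
#' microvascular resistance connecting them (`R_p = 0.9 R_tot`, so the
#' three sum to `R_tot` exactly), and compartment compliances chosen so
#' that the peripheral filling/emptying time constant `R_p C_a = R_p C_v`
#' equals `tau` (default 0.5 s). With `enable_compliance = FALSE` both
#' compliances are zero and the ladder degenerates to a series resistor --
#' the configuration used while fitting `R_tot`.
#'
#' @param R_tot total peripheral resistance, Pa.s/m^3.
#' @param tau peripheral time constant `R_p * C`, s.
#' @param enable_compliance logical; `FALSE` forces `C_a = C_v = 0`.
#' @return an object of class `avg_bc_params` with elements `Z_a`, `R_p`,
#'   `Z_v`, `C_a`, `C_v`, `R_tot`, `tau` and `provenance`.
#' @examples
#' p <- split_parameters(100)
#' c(p$Z_a, p$R_p, p$Z_v)  # 5 90 5
#' @export
split_parameters <- function(R_tot, tau = 0.5, enable_compliance = TRUE) {
  check_positive(R_tot, "R_tot")
  check_positive(tau, "tau")
  R_p <- 0.9 * R_tot
  Z <- (R_tot - R_p) / 2                 # so Z_a + R_p + Z_v == R_tot exactly
  C <- if (enable_compliance) tau / R_p else 0
  structure(list(Z_a = Z, R_p = R_p, Z_v = Z, C_a = C, C_v = C,
                 R_tot = R_tot, tau = tau,
                 provenance = list(split = c(Z_a = 0.05, R_p = 0.9,
                                             Z_v = 0.05),
                                   compliance_enabled = enable_compliance)),
            class = "avg_bc_params")
}

#' @export
print.avg_bc_params <- function(x, ...) {
  cat(sprintf(
    "<avg_bc_params> R_tot %.4g Pa.s/m^3 (Z_a %.3g | R_p %.3g | Z_v %.3g), C %.3g m^3/Pa\n",
    x$R_tot, x$Z_a, x$R_p, x$Z_v, x$C_a))
  invisible(x)
}

#' Distal boundary-condition models
#'
#' Three interchangeable models for the vasculature distal to the flow
#' domain, all exposing the same pressure-in/flow-out stepping contract
#' ([bc_step()]):
#' \describe{
#'   \item{zero-flow (`make_zero_flow_bc`)}{peripheral flow neglected:
#'     exchange flows identically zero.}
#'   \item{arteriovenous coupling (`make_avc_bc`)}{compliant distal
#'     arterial and venous compartments joined by a resistive
#'     microvasculature and coupled to the domain through characteristic
#'     impedances.}
#'   \item{coupling with collaterals (`make_avce_bc`)}{as above, plus an
#'     adjustable collateral resistor `R_c` from the venous compartment to
#'     the common venous return; `R_c` is re-tuned every step by
#'     [update_collateral_resistance()] so flow splits evenly between the
#'     simulated vein and the collaterals.}
#' }
#'
#' @param params an [split_parameters()] object.
#' @param R_c_init initial collateral resistance, Pa.s/m^3 (`NULL` lets
#'   the loop simulator initialise it at the even-split value found by a
#'   steady-state root-find, i.e. at the controller's fixed point).
#' @param relaxation controller relaxation exponent in (0, 1].
#' @param ctrl_timescale controller action timescale, s: each time step
#'   applies the multiplicative law with exponent
#'   `relaxation * dt / ctrl_timescale`, so the controller behaves as a
#'   damped integral loop independent of the step size. The flows it
#'   compares are one-cycle running means maintained by the loop
#'   simulator: the venous-inlet flow of a pulsatile run reverses during
#'   part of the cycle, so the instantaneous ratio has no fixed point,
#'   whereas the one-period running mean cancels every cardiac harmonic
#'   exactly and makes the even split well defined (equal running means =
#'   equal cycle means).
#' @param clamp_factor `R_c` is clamped to
#'   `[R_c_init / clamp_factor, R_c_init * clamp_factor]`.
#' @return an object of class `avg_bc_model`.
#' @export
make_zero_flow_bc <- function() {
  structure(list(kind = "zero_flow", params = NULL),
            class = c("avg_bc_zero", "avg_bc_model"))
}

#' @rdname make_zero_flow_bc
#' @export
make_avc_bc <- function(params) {
  stopifnot(inherits(params, "avg_bc_params"))
  structure(list(kind = "avc", params = params),
            class = c("avg_bc_avc", "avg_bc_model"))
}

#' @rdname make_zero_flow_bc
#' @export
make_avce_bc <- function(params, R_c_init = NULL, relaxation = 0.5,
                         ctrl_timescale = 0.5, clamp_factor = 1e3) {
  stopifnot(inherits(params, "avg_bc_params"))
  if (!is.null(R_c_init)) check_positive(R_c_init, "R_c_init")
  if (relaxation <= 0 || relaxation > 1)
    stopf("'relaxation' must lie in (0, 1]")
  check_positive(ctrl_timescale, "ctrl_timescale")
  structure(list(kind = "avce", params = params, R_c_init = R_c_init,
                 relaxation = relaxation, ctrl_timescale = ctrl_timescale,
                 clamp_factor = clamp_factor),
            class = c("avg_bc_avce", "avg_bc_model"))
}

#' @export
print.avg_bc_model <- function(x, ...) {
  cat(sprintf("<avg_bc_model> %s\n", x$kind))
  invisible(x)
}

#' Initial state for a boundary-condition model
#'
#' @param model an `avg_bc_model`.
#' @param p_Ca,p_Cv initial compartment pressures, Pa.
#' @return a `bc_state` list (`p_Ca`, `p_Cv`, `R_c`, `time`, `n_freezes`).
#' @export
bc_init_state <- function(model, p_Ca = 0, p_Cv = 0) {
  R_c <- NA_real_
  if (inherits(model, "avg_bc_avce"))
    R_c <- model$R_c_init %||% NA_real_
  list(p_Ca = p_Ca, p_Cv = p_Cv, R_c = R_c, time = 0,
       n_freezes = 0L, q_ven_prev = NA_real_, q_col_prev = NA_real_)
}

#' Boundary conductances exposed to the flow solver
#'
#' Part of the coupling contract: the flow solver embeds these
#' admittances (1/Z) at its boundary nodes so that the explicit
#' sub-iteration between domain and boundary model only has to relax the
#' (slowly varying) compartment pressures, not the stiff impedance flows.
#'
#' @param model an `avg_bc_model`.
#' @return list with `y_art` and `y_ven`, 1/(Pa.s/m^3).
#' @export
bc_conductances <- function(model) {
  if (inherits(model, "avg_bc_zero")) return(list(y_art = 0, y_ven = 0))
  list(y_art = 1 / model$params$Z_a, y_ven = 1 / model$params$Z_v)
}

#' Advance a boundary-condition model by one time step
#'
#' The stepping contract: given the domain pressures at the arterial
#' outlet (`p_art`) and venous inlet (`p_ven`), advance the internal
#' compartment pressures over `dt` with an unconditionally stable implicit
#' (backward-Euler) update and return the exchange flows. Sign convention:
#' `q_art_out` leaves the domain at the arterial outlet, `q_ven_in` enters
#' it at the venous inlet, `q_collateral` bypasses the domain towards the
#' common venous return at pressure `p_ven_out`.
#'
#' For the collateral-extended model, `R_c` must have been initialised
#' (see [make_avce_bc()]); the controller itself is the caller's
#' responsibility via [update_collateral_resistance()] (the loop simulator
#' applies it before every step).
#'
#' @param model an `avg_bc_model`.
#' @param state state list from [bc_init_state()] or a previous step.
#' @param p_art,p_ven domain boundary pressures, Pa.
#' @param dt time step, s.
#' @param p_ven_out common venous return pressure, Pa.
#' @return list with `exchange` (`q_art_out`, `q_ven_in`, `q_collateral`,
#'   `q_micro`, all m^3/s) and the advanced `state`.
#' @export
bc_step <- function(model, state, p_art, p_ven, dt, p_ven_out = 0) {
  UseMethod("bc_step")
}

#' @export
bc_step.avg_bc_zero <- function(model, state, p_art, p_ven, dt,
                                p_ven_out = 0) {
  state$time <- state$time + dt
  list(exchange = list(q_art_out = 0, q_ven_in = 0, q_collateral = 0,
                       q_micro = 0),
       state = state)
}

bc_step_ladder <- function(params, state, p_art, p_ven, dt, p_ven_out,
                           R_c = Inf) {
  check_positive(dt, "dt")
  g_c <- if (is.finite(R_c)) 1 / R_c else 0
  m11 <- params$C_a / dt + 1 / params$Z_a + 1 / params$R_p
  m12 <- -1 / params$R_p
  m22 <- params$C_v / dt + 1 / params$R_p + 1 / params$Z_v + g_c
  r1 <- params$C_a / dt * state$p_Ca + p_art / params$Z_a
  r2 <- params$C_v / dt * state$p_Cv + p_ven / params$Z_v +
    g_c * p_ven_out
  det <- m11 * m22 - m12 * m12
  p_Ca <- (r1 * m22 - m12 * r2) / det
  p_Cv <- (m11 * r2 - m12 * r1) / det
  list(p_Ca = p_Ca, p_Cv = p_Cv,
       q_art_out = (p_art - p_Ca) / params$Z_a,
       q_micro = (p_Ca - p_Cv) / params$R_p,
       q_ven_in = (p_Cv - p_ven) / params$Z_v,
       q_collateral = g_c * (p_Cv - p_ven_out))
}

#' @export
bc_step.avg_bc_avc <- function(model, state, p_art, p_ven, dt,
                               p_ven_out = 0) {
  s <- bc_step_ladder(model$params, state, p_art, p_ven, dt, p_ven_out,
                      R_c = Inf)
  state$p_Ca <- s$p_Ca; state$p_Cv <- s$p_Cv
  state$time <- state$time + dt
  list(exchange = list(q_art_out = s$q_art_out, q_ven_in = s$q_ven_in,
                       q_collateral = 0, q_micro = s$q_micro),
       state = state)
}

#' @export
bc_step.avg_bc_avce <- function(model, state, p_art, p_ven, dt,
                                p_ven_out = 0) {
  if (!is.finite(state$R_c))
    stopf("AVCE model stepped before R_c was initialised")
  s <- bc_step_ladder(model$params, state, p_art, p_ven, dt, p_ven_out,
                      R_c = state$R_c)
  state$p_Ca <- s$p_Ca; state$p_Cv <- s$p_Cv
  state$time <- state$time + dt
  state$q_ven_prev <- s$q_ven_in
  state$q_col_prev <- s$q_collateral
  list(exchange = list(q_art_out = s$q_art_out, q_ven_in = s$q_ven_in,
                       q_collateral = s$q_collateral, q_micro = s$q_micro),
       state = state)
}

#' Per-step collateral resistance controller
#'
#' Multiplicative update driving the collateral flow towards the flow
#' through the simulated vein: `R_c <- R_c * (q_collateral /
#' q_ven_in)^relaxation`, clamped to the configured range. Equal
#' instantaneous flows are the fixed point. A non-positive `q_ven_in`
#' (flow reversal at the venous inlet) freezes `R_c` for that step and is
#' counted in the state.
#'
#' @param state bc state list holding `R_c`.
#' @param q_ven_in,q_collateral previous-step flows, m^3/s.
#' @param relaxation exponent in (0, 1].
#' @param clamp length-2 numeric, allowed `[min, max]` for `R_c`.
#' @return the updated state.
#' @export
update_collateral_resistance <- function(state, q_ven_in, q_collateral,
                                         relaxation = 0.5,
                                         clamp = c(0, Inf)) {
  if (!is.finite(q_ven_in) || !is.finite(q_collateral))
    stopf("controller flows must be finite")
  if (q_ven_in <= 0) {
    state$n_freezes <- state$n_freezes + 1L
    return(state)
  }
  if (q_collateral <= 0) {
    # collateral stalled: relax R_c downwards by the clamp step instead of
    # taking log of a non-positive ratio
    state$R_c <- max(clamp[1], state$R_c * 0.5)
    return(state)
  }
  r <- state$R_c * (q_collateral / q_ven_in)^relaxation
  state$R_c <- min(clamp[2], max(clamp[1], r))
  state
}

#' Serialize boundary-condition parameters to JSON
#'
#' Values, units and provenance (split fractions, time constant,
#' compliance flag) are written so a fitted parameter set can be reused by
#' external solvers.
#'
#' @param params an `avg_bc_params`.
#' @param path file path.
#' @return `read_bc_params_json` returns an `avg_bc_params`.
#' @export
write_bc_params_json <- function(params, path) {
  x <- list(units = list(resistance = "Pa.s/m^3", compliance = "m^3/Pa",
                         tau = "s"),
            R_tot = params$R_tot, Z_a = params$Z_a, R_p = params$R_p,
            Z_v = params$Z_v, C_a = params$C_a, C_v = params$C_v,
            tau = params$tau, provenance = params$provenance)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bc_params_json
#' @export
read_bc_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  split_parameters(x$R_tot, tau = x$tau,
                   enable_compliance = isTRUE(x$provenance$compliance_enabled))
}
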