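#' Run configuration
#'
#' Assembles and validates the configuration for a full pipeline run.
#' Unknown fields are rejected; all defaults are filled in so the
#' effective configuration (what actually ran) can be logged and written
#' next to the results. Units at this interface: mm, degrees, mL/min, s.
#'
#' @param config named list (possibly nested) overriding defaults, or a
#'   path to a JSON file with the same structure.
#' @return object of class `avg_run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defaults <- list(
    geometry = list(mode = "idealized",
                    artery_diameter = 6.6, vein_diameter = 7.7,
                    graft_diameter = 6.0,
                    proximal_multiple = 7.5, distal_multiple = 3.25,
                    arterial_angle = 45, venous_angle = 45,
                    centerline_file = NULL),
    fluid = list(dynamic_viscosity = 3.5e-3, density = 1050),
    bc = list(type = "avc", target_flow = 73, tau = 0.5,
              relaxation = 0.5),
    waveform = list(preset = "graft_inlet", mean_flow = 990 + 73,
                    pulsatility = 1.5, harmonics = 5, period = 1.0,
                    file = NULL),
    simulation = list(dt = 1e-4, n_cycles = 3, sub_iter = 2),
    metrics = list(enabled = TRUE, fixture_pattern = "mixed_region",
                   frac_high = 0.3),
    seed = 1L)
  for (nm in names(config))
    if (!nm %in% names(defaults))
      stopf("unknown config section '%s'", nm)
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$bc$type %in% c("zf", "avc", "avce"))
    stopf("bc type must be one of zf, avc, avce")
  if (!cfg$geometry$mode %in% c("idealized", "realistic"))
    stopf("geometry mode must be 'idealized' or 'realistic'")
  if (cfg$geometry$mode == "realistic" &&
      is.null(cfg$geometry$centerline_file))
    stopf("realistic mode needs geometry$centerline_file")
  structure(cfg, class = "avg_run_config")
}

run_log_new <- function() {
  env <- new.env(parent = emptyenv())
  env$lines <- character(0)
  env
}

log_event <- function(log, fmt, ...) {
  log$lines <- c(log$lines,
                 sprintf("[%s] %s", format(Sys.time(), "%H:%M:%OS2"),
                         sprintf(fmt, ...)))
  invisible(log)
}

#' Run the full modelling pipeline
#'
#' Geometry construction, boundary-model fitting, loop simulation and
#' metric computation, with every stage's outputs written to `out_dir`:
#' `centerlines.csv`, `surface.stl`/`surface.vtk`, `bc_params.json`,
#' `result.csv`, `exchange.csv`, `summary.json` and `run.log`. The
#' summary (means, pulsatility, waveform classification, metric area
#' fractions, QC counters) is deterministic given the same configuration
#' and seed; timestamps only appear in the log.
#'
#' @param config an [run_config()] (or a list / JSON path accepted by it).
#' @param out_dir output directory (created if missing).
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  if (!inherits(config, "avg_run_config")) config <- run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- run_log_new()
  stage <- function(name, expr) {
    log_event(log, "stage %s: start", name)
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s (check the corresponding config section)",
            name, conditionMessage(e)))
  }
  g <- config$geometry
  specs <- list(
    artery = vessel_spec("artery", g$artery_diameter,
                         g$proximal_multiple, g$distal_multiple),
    vein = vessel_spec("vein", g$vein_diameter,
                       g$proximal_multiple, g$distal_multiple),
    graft = vessel_spec("graft", g$graft_diameter))

  tree <- stage("geometry", {
    t0 <- if (g$mode == "idealized")
      build_idealized_centerlines(specs, list(
        arterial = anastomosis_spec(g$arterial_angle),
        venous = anastomosis_spec(g$venous_angle)))
    else import_centerlines(g$centerline_file)
    trim_and_extend(t0, specs)
  })
  write_centerlines(tree, file.path(out_dir, "centerlines.csv"))
  surf <- stage("surface", sweep_and_join(tree))
  write_surface_stl(surf, file.path(out_dir, "surface.stl"))
  write_surface_vtk(surf, file.path(out_dir, "surface.vtk"))
  log_event(log, "geometry: %d surface faces, angles %.2f / %.2f deg",
            nrow(surf$faces), measure_anastomosis_angle(tree, "arterial"),
            measure_anastomosis_angle(tree, "venous"))

  wf_cfg <- config$waveform
  inlet <- stage("waveform", {
    if (!is.null(wf_cfg$file)) read_waveform_csv(wf_cfg$file)
    else make_inlet_waveform(mean_flow = wf_cfg$mean_flow,
                             pulsatility = wf_cfg$pulsatility,
                             period = wf_cfg$period,
                             harmonics = wf_cfg$harmonics,
                             seed = config$seed)
  })

  fluid <- fluid_props(config$fluid$dynamic_viscosity, config$fluid$density)
  log_event(log,
            "fluid: viscosity %.3g Pa.s (blood, high-shear Newtonian), density %g kg/m^3",
            fluid$dynamic_viscosity, fluid$density)

  bc <- stage("fit-bc", {
    if (config$bc$type == "zf") make_zero_flow_bc()
    else {
      loop0 <- assemble_loop(tree, fluid, make_zero_flow_bc(), inlet)
      R_tot <- fit_total_resistance(loop0, config$bc$target_flow)
      log_event(log, "fitted R_tot = %.6g Pa.s/m^3 (peripheral %.3f mL/min)",
                R_tot, attr(R_tot, "achieved_flow"))
      params <- split_parameters(as.numeric(R_tot), tau = config$bc$tau)
      write_bc_params_json(params, file.path(out_dir, "bc_params.json"))
      if (config$bc$type == "avc") make_avc_bc(params)
      else make_avce_bc(params, relaxation = config$bc$relaxation)
    }
  })

  loop <- assemble_loop(tree, fluid, bc, inlet)
  res <- stage("simulate",
               simulate_loop(loop, n_cycles = config$simulation$n_cycles,
                             dt = config$simulation$dt,
                             sub_iter = config$simulation$sub_iter))
  write_loop_result_csv(res, file.path(out_dir, "result.csv"))
  write_exchange_csv(res, file.path(out_dir, "exchange.csv"))
  if (res$n_freezes > 0)
    log_event(log, "warning: collateral controller frozen on %d step(s)",
              res$n_freezes)

  means <- mean_branch_flows(res)
  ix <- cycle_indices(res, res$analysis_cycle)
  boundary_series <- list(
    arterial_inlet = res$flows[ix, "proximal_artery"],
    arterial_outlet = res$flows[ix, "distal_artery"],
    venous_inlet = res$flows[ix, "distal_vein"],
    venous_outlet = res$flows[ix, "proximal_vein"])
  pi_safe <- function(x) if (abs(mean(x)) > 1e-15) pulsatility_index(x)
  else NA_real_
  summary <- list(
    config = unclass(config),
    mean_flows_mlmin = as.list(means),
    pulsatility_index = lapply(boundary_series, pi_safe),
    classification = lapply(boundary_series, function(x)
      tryCatch(classify_waveform(x), error = function(e) NA_character_)),
    periodic = res$periodic,
    max_balance_residual = res$max_balance_residual,
    n_collateral_freezes = res$n_freezes)

  if (isTRUE(config$metrics$enabled)) {
    fx <- stage("metrics",
                make_wss_fixture(config$metrics$fixture_pattern,
                                 seed = config$seed,
                                 frac_high = config$metrics$frac_high))
    ms <- metric_summary(fx$field)
    summary$metric_area_fractions <- as.list(ms[1, -1])
    summary$metric_qc <- list(
      n_undefined_osi = attr(ms, "n_undefined_osi"),
      truth_frac_high = fx$truth$frac_high_percent)
    log_event(log, "metrics: %d undefined-OSI point(s) excluded",
              attr(ms, "n_undefined_osi"))
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  log_event(log, "run complete")
  writeLines(log$lines, file.path(out_dir, "run.log"))
  invisible(summary)
}
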