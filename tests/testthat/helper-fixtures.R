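# Shared builders, memoized so expensive objects are constructed once per
# test session.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

default_tree <- function() memo("tree", {
  trim_and_extend(build_idealized_centerlines())
})

default_inlet <- function() memo("inlet", {
  make_inlet_waveform(preset = "graft_inlet")
})

default_loop <- function() memo("loop", {
  assemble_loop(default_tree(), inlet = default_inlet())
})

fitted_params <- function() memo("params", {
  split_parameters(as.numeric(fit_total_resistance(default_loop(), 73)))
})

avc_result <- function() memo("avc_result", {
  simulate_loop(set_loop_bc(default_loop(), make_avc_bc(fitted_params())),
                n_cycles = 3, dt = 1e-4)
})

avce_result <- function() memo("avce_result", {
  simulate_loop(set_loop_bc(default_loop(), make_avce_bc(fitted_params())),
                n_cycles = 3, dt = 1e-4)
})

zf_result <- function() memo("zf_result", {
  simulate_loop(default_loop(), n_cycles = 3, dt = 1e-4)
})

analysis_flows <- function(result, branch) {
  spc <- round(result$period / result$dt)
  ix <- (nrow(result$flows) - spc):nrow(result$flows)
  result$flows[ix, branch]
}

# Analytic input admittance of the coupling ladder (arterial side driven,
# venous side grounded): the independent oracle for the stepping contract.
ladder_admittance <- function(params, f_hz) {
  w <- 2 * pi * f_hz
  Zin <- params$Z_a +
    1 / (1i * w * params$C_a +
           1 / (params$R_p + 1 / (1i * w * params$C_v + 1 / params$Z_v)))
  1 / Zin
}

# Toy five-segment loop with explicit resistances (inertances ~ 0 unless
# given), for closed-form network checks.
toy_loop <- function(R_da, R_g, R_dv, R_pv, R_pa = 1, inertance = 1e-12,
                     inlet = NULL) {
  seg <- function(label, R) {
    s <- segment_impedance(1, 1e-2, fluid_props(), label)
    s$resistance <- R
    s$inertance <- inertance
    s
  }
  if (is.null(inlet)) inlet <- make_inlet_waveform(1000, pulsatility = 0)
  loop_model(list(proximal_artery = seg("proximal_artery", R_pa),
                  distal_artery = seg("distal_artery", R_da),
                  graft = seg("graft", R_g),
                  distal_vein = seg("distal_vein", R_dv),
                  proximal_vein = seg("proximal_vein", R_pv)),
             inlet = inlet)
}
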