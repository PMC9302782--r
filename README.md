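# avghemo

Desk-scale modelling of arteriovenous graft (AVG) hemodynamics in R.

Prosthetic grafts connecting an artery to a vein are the fallback
vascular access for hemodialysis, and most of them fail within two years
because neointimal hyperplasia narrows the vein near the graft–vein
anastomosis. Disturbed flow and non-physiological wall shear stress (WSS)
at that anastomosis are the leading suspected triggers, so new graft
designs are screened with computational hemodynamics — and the outcome of
such screening depends heavily on how the geometry and the vasculature
*beyond* the simulated domain are represented. `avghemo` packages that
modelling layer so it can be studied, tested and reused without a 3D CFD
solver:

* **Geometry** — parametrized idealized AVG circuits (straight artery and
  vein joined by a smooth graft loop meeting each vessel at a prescribed
  anastomotic angle, 45° by default) and centerline-based "realistic"
  circuits imported from CSV/VTK polylines. Host vessels are trimmed to
  7.5 diameters proximal and 3.25 diameters distal of their anastomosis,
  then straight flow extensions double each segment. Circular
  cross-sections are swept into watertight labelled surface meshes.
* **Distal boundary models** — three interchangeable lumped models of the
  peripheral vasculature: zero-flow (ZF), arteriovenous coupling (AVC: a
  `Z_a — C_a — R_p — C_v — Z_v` ladder joining the arterial outlet to the
  venous inlet), and AVC extended with an adaptive collateral resistor
  `R_c` (AVCE). The total peripheral resistance `R_tot = Z_a + R_p + Z_v`
  is fitted by root-finding so the steady peripheral flow matches a
  measured target; afterwards `R_p = 0.9 R_tot`,
  `Z_a = Z_v = 0.05 R_tot`, and compliances satisfy
  `R_p C_a = R_p C_v = 0.5 s`.
* **Loop surrogate** — a resistance–inertance (Poiseuille) network of the
  five vessel segments, coupled to any of the boundary models through a
  pressure-in/flow-out stepping contract, integrated semi-implicitly at
  0.1 ms over three cardiac cycles.
* **Metrics** — time-averaged WSS `TAWSS = (1/T)∫|τ| dt`, peak WSS
  `WSS_max = max_t |τ|`, oscillatory shear index
  `OSI = ½(1 − |∫τ dt| / ∫|τ| dt)`, area fractions against the
  disturbed-WSS thresholds (TAWSS < 0.1 Pa; 7 Pa < WSS_max ≤ 40 Pa;
  WSS_max > 40 Pa; OSI > 0.25), the venous perianastomotic region mask
  (−2.5 cm distal to +3.0 cm proximal), Reynolds-decomposition
  perturbation RMS `ũ_RMS`, and its cross-sectional median profile
  `ũ_RMS,50`.
* **Synthetic fixtures** — seed-deterministic generators for pulsatile
  inlet waveforms (exact mean, exact pulsatility index), toy centerline
  trees with recorded junction truth, and WSS/velocity field time-series
  with analytically known metric values, so every component is testable
  without clinical data.

## Worked example

```r
library(avghemo)

tree  <- trim_and_extend(build_idealized_centerlines())
inlet <- make_inlet_waveform(preset = "graft_inlet")   # 990 + 73 mL/min mean
loop  <- assemble_loop(tree, inlet = inlet)

R_tot  <- fit_total_resistance(loop, target_flow = 73) # brachial mean, mL/min
params <- split_parameters(as.numeric(R_tot))
params
#> <avg_bc_params> R_tot 5.95e+07 Pa.s/m^3 (Z_a 2.97e+06 | R_p 5.35e+07 | Z_v 2.97e+06), C 9.34e-09 m^3/Pa

res <- simulate_loop(set_loop_bc(loop, make_avc_bc(params)))
res
#> <avg_loop_result> 3 cycles @ dt 0.0001 s, periodic: TRUE
#>   proximal_artery    1063.00 mL/min
#>   distal_artery        73.00 mL/min
#>   graft               990.00 mL/min
#>   distal_vein          73.00 mL/min
#>   proximal_vein      1063.00 mL/min
#>   collateral            0.00 mL/min
```

The fitted loop sends exactly the preoperative brachial flow
(73 mL/min) to the periphery while the graft carries the remaining
990 mL/min. On the analysis cycle the arterial-outlet waveform is
triphasic (fast systolic acceleration, early-diastolic retrograde dip,
late slow antegrade flow) and the venous inlet is far less pulsatile:

```r
spc <- round(res$period / res$dt)
ix  <- (nrow(res$flows) - spc):nrow(res$flows)
classify_waveform(res$flows[ix, "distal_artery"])
#> [1] "triphasic"
pulsatility_index(res$flows[ix, "distal_vein"])
#> [1] 7.58   # vs 16.5 at the arterial outlet
```

WSS metrics run on any field time-series; here a synthetic fixture whose
ground truth puts 30% of the area above the 7 Pa threshold:

```r
fx <- make_wss_fixture("mixed_region", frac_high = 0.3)
metric_summary(fx$field)
#> <avg_metric_summary> area fractions (%)
#>  region WSS_low WSS_high WSS_very_high OSI_high
#>   total       0       30             0        0
```

`run_pipeline(run_config(), "out/")` chains all stages (geometry →
surface → fit → simulation → metrics) and writes CSV/STL/VTK/JSON
artifacts plus a run log; `inst/cli/avg.R` is a thin command-line wrapper
over the same functions.

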