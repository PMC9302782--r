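---
title: "Modelling arteriovenous graft hemodynamics at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling arteriovenous graft hemodynamics at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avghemo)
```

## The problem

Arteriovenous grafts (AVGs) for hemodialysis fail predominantly through
neointimal hyperplasia at the graft–vein anastomosis, and the
hemodynamic quantities implicated in that process — low and oscillatory
wall shear stress (WSS), very high WSS, transitional flow — are exactly
the quantities most sensitive to two modelling choices: how realistic the
graft geometry is, and how the vasculature distal to the simulated domain
is represented. `avghemo` implements that modelling layer (geometry
parametrization, distal boundary models with their calibration rules, a
lumped surrogate of the flow loop, and the disturbed-flow metric suite)
as ordinary, testable R functions. The 3D Navier–Stokes problem itself is
deliberately out of scope: everything here either feeds such a solver,
stands in for it at desk scale, or post-processes its fields.

## Geometry model

An AVG circuit is three labelled centerline branches (artery, vein,
graft) with per-branch constant radius, plus two anastomosis reference
points. The idealized build places a straight artery along +x (its
anastomosis at the origin) and a straight parallel vein at
`y = loop_width` (40 mm default), joined by a cubic-Bezier graft whose
endpoint tangents realise the anastomotic angles exactly; 45° on both
sides is the default, the classic configuration in the modelling
literature. Defaults for the lumina are 6.6 mm (artery), 7.7 mm (vein)
and 6 mm (graft) — upper-arm loop-graft dimensions measured by
preoperative ultrasound.

Two clinically motivated rules shape the hosts. First, trimming: each
host vessel is cut to 7.5 diameters on the proximal side of its
anastomosis and 3.25 diameters on the distal side, so circuits built
from different images are comparable. Second, flow extensions: a
straight, tangent-continuous extension doubles each trimmed segment, so
boundary artefacts (plug-like inflow, reflected waves, prescribed-pressure
caps) sit far from the anastomosis. `trim_and_extend()` is idempotent —
re-applying it re-cuts to the same arc lengths and rebuilds identical
extensions — which the test suite checks directly.

Surfaces are produced by sweeping circular cross-sections along each
branch with minimal-twist frames (`sweep_and_join()`). Each branch is a
closed manifold triangle mesh with planar caps; host caps are labelled
`cap:arterial_inlet`, `cap:arterial_outlet`, `cap:venous_inlet`,
`cap:venous_outlet`, and graft end faces `junction:arterial` /
`junction:venous`. The branch tubes meet at the shared anastomosis
references but are *not* merged by a boolean union: a robust mesh CSG
union with junction smoothing is a substantial computational-geometry
subsystem in its own right, and nothing downstream in this package needs
a conformal junction — the network surrogate uses only segment lengths
and diameters, and the metric suite operates on arbitrary labelled point
sets. The non-conformal junction is therefore a documented design
boundary: meshes exported for external CFD should be unioned in the
meshing tool that will volume-mesh them anyway.

Numerical choices: centerlines are resampled at 0.25 mm; tangents use
central secants (1 mm window) in branch interiors and one-sided
second-order differences at the ends, which keeps measured anastomotic
angles within ~0.05° of the requested value; sweeps refuse to build when
the local centerline curvature radius drops below the tube radius
(self-intersection); cap/ring resolution defaults to 1 mm spacing and 32
vertices per ring, at which a cylinder's wall area is within 1% of
`2πrL` (and converges monotonically with angular resolution).

The "realistic" path accepts centerline polylines from CSV or VTK legacy
polydata, collapses duplicate points, resamples, and locates the
anastomoses as closest-approach points between graft and host polylines.
Since no patient centerlines ship with the package, the fixture generator
provides a tortuous stand-in: a smooth seed-deterministic sinusoidal warp
applied to the whole idealized circuit at once (so branches still meet at
their junctions), with the exact post-warp junction coordinates recorded
as ground truth. With zero warp amplitude it reduces to the idealized
loop.

## Distal boundary-condition models

Three models of the vasculature beyond the arterial outlet and venous
inlet share one stepping contract.

**Zero-flow (ZF).** Peripheral flow neglected; exchange flows identically
zero. This is the simplification the package exists to interrogate: in a
rigid loop it forces venous outflow to equal arterial inflow pointwise.

**Arteriovenous coupling (AVC).** The peripheral vasculature is a ladder:
characteristic impedance `Z_a` into a compliant distal-arterial
compartment `C_a`, microvascular resistance `R_p` to a compliant
distal-venous compartment `C_v`, impedance `Z_v` back into the simulated
vein. Calibration follows a two-step rule. First `R_tot = Z_a + R_p +
Z_v` is fitted with compliances set to zero and the cycle-mean inlet flow
prescribed, by a bracketing root-finder on `log10(R_tot)`
(`fit_total_resistance()`, tolerance 0.1 mL/min on the peripheral flow;
the bracket spans 1e2–1e15 Pa·s/m³).
The physiological target is the preoperatively measured brachial mean
flow (73 mL/min in the default configuration): access creation should not
steal perfusion from the hand. Then `split_parameters()` distributes
`R_p = 0.9 R_tot`, `Z_a = Z_v = 0.05 R_tot` (the sum reproduces `R_tot`
to the last bit) and sets `C_a = C_v = τ / R_p` with `τ = 0.5 s`, the
standard peripheral time constant.

**AVC with collaterals (AVCE).** A collateral resistor `R_c` drains the
venous compartment directly to the common venous return, representing
collateral veins in parallel with the simulated vein. `R_c` is re-tuned
at every time step by a multiplicative controller,
`R_c ← R_c (q_collateral / q_ven)^relaxation`, whose fixed point is an
even flow split. Two implementation details matter and are deliberate:

* *What flows the controller compares.* The venous-inlet exchange flow of
  a pulsatile run reverses during a substantial part of the cycle, so the
  instantaneous flow ratio has no fixed point and a controller driven by
  it freezes and drifts. The controller therefore compares one-cycle
  running means, which cancel every cardiac harmonic exactly and equal
  the cycle means in the periodic regime; it engages once a full cycle of
  history exists.
* *Gain scheduling.* The per-step exponent is
  `relaxation · dt / ctrl_timescale` (defaults 0.5 and 0.5 s), making the
  controller a damped integral loop whose behaviour is independent of the
  step size. Its initial value is found by root-finding the steady-state
  even split, so the controller starts at (not merely near) its fixed
  point; clamps at 10³ times either side guard against degenerate
  transients. On the default three-cycle run the vein/collateral
  cycle-mean difference settles near 0.002 mL/min, well inside the
  0.1 mL/min even-split tolerance.

**Stepping contract.** `bc_step(model, state, p_art, p_ven, dt)` advances
the compartment pressures with an unconditionally stable backward-Euler
update (a 2×2 linear solve, exact also at zero compliance) and returns
the exchange flows; `bc_conductances()` exposes the boundary admittances
`1/Z`. The admittances must be embedded in the flow solver's nodal
system — a flow-only explicit exchange diverges because the segment
inertance term `L/dt` dwarfs `Z` at 0.1 ms steps — after which the only
explicitly relaxed quantities are the slowly varying compartment
pressures, with a per-step coupling gain of order 10⁻² when compliances
are enabled. Two sub-iterations per step are then ample. The same
contract suits an external 3D solver; the discrete charge balance
`C Δp = dt (q_in − q_out)` holds to ~1e-10 relative, and the stepped
frequency response matches the analytic ladder admittance within 0.03%
in amplitude and 0.01° in phase over 1–10 Hz.

## The loop surrogate

The flow domain between the boundaries is replaced by a five-segment
resistance–inertance network (Poiseuille resistance `8μL/(πr⁴)`,
inertance `ρL/(πr²)` per segment), assembled directly from the
centerline tree. Blood is Newtonian with viscosity 3.5 mPa·s and density
1050 kg/m³. The venous outlet is held at 0 mmHg — only pressure
differences matter in a rigid loop. A pulsatile flow is prescribed at the
arterial inlet; the default preset sums the postoperative graft flow and
the preoperative brachial flow (990 + 73 = 1063 mL/min, printed as
1.06×10³).

The inlet waveform's *shape* is not published anywhere, so the generator
synthesizes the standard arterial morphology: a raised-cosine systolic
ejection wave plus a smaller, broader late-diastolic (dicrotic) forward
wave, band-limited to 5 harmonics, with the cycle mean and pulsatility
index (default 1.5) enforced exactly. The dicrotic component is not
cosmetic: the documented downstream physics — a triphasic arterial-outlet
waveform — requires some late-diastolic forward drive at the inlet, and
upper-limb Doppler traces show it. A flat-bottomed single pulse yields an
outlet that stays slightly retrograde through diastole ("biphasic") in
this surrogate; users studying waveform-shape sensitivity can set
`dicrotic_amp = 0`. The cardiac period (never stated clinically) defaults
to 1.0 s.

Integration is semi-implicit at `dt = 0.1 ms`: segment flows by backward
differences, boundary admittances in the 4-node nodal matrix (constant,
factorized once), compartments stepped implicitly within the
sub-iteration. Because the loop plus boundary model is linear and
time-invariant, the run is initialised at its exact periodic orbit by a
frequency-domain solve per inlet harmonic. This removes the start-up
transient of the slow peripheral charging mode (`R_p C = 0.5 s`), which
would otherwise still bias the third cycle by ~1.5%; with it, the
standard protocol — three cycles, the last analysed — is already periodic
(cycle-2 vs cycle-3 RMS difference below 1%), node mass balance holds to
~1e-20, and the AVC cycle means at arterial outlet and venous inlet agree
within 0.5% (the compartments store no net volume over a period).

What the surrogate reproduces and what it cannot: waveform phenomena
(ZF inlet/outlet identity, the AVC phase shift, triphasic outlet,
low-pulsatility monophasic venous inflow, the AVCE even split) and mean
flow distributions are in scope. Quantities produced by 3D flow
separation — anastomotic jet dynamics, 40–45 Hz vortex shedding,
pressure-drop magnitudes, WSS area fractions of a real anastomosis — are
not; the surrogate ignores minor losses and convective acceleration, and
its arterial-outlet pulsatility is larger than a 3D domain's because the
fitted `R_tot` (hence `Z_a`) scales with the surrogate's small loop
pressure drop. The metric suite exists precisely so such fields can be
ingested from a full solver instead.

`classify_waveform()` makes the waveform vocabulary operational:
monophasic if the flow never dips to ≤5% of its systolic peak; otherwise
triphasic if, between the dip and the upstroke into the next systole
(detected as the trailing strictly monotone rise), flow recovers to at
least 10% of the peak; otherwise biphasic. Both thresholds are exposed.

## Disturbed-flow metrics

For a WSS vector series `τ(t, x)` on one cycle of period `T`, sampled
uniformly (half-open grid, trapezoidal quadrature with periodic wrap —
which collapses to the sample mean, so a zero-mean sinusoid integrates
to exactly zero):

* `TAWSS(x) = (1/T) ∫ |τ| dt`,
* `WSS_max(x) = max_t |τ|`,
* `OSI(x) = ½ (1 − |∫ τ dt| / ∫ |τ| dt)` with the vector integral in the
  numerator: 0 for unidirectional shear, 0.5 for purely oscillatory
  shear. Points with zero total shear have no defined OSI; they are
  returned as `NA`, excluded from area fractions, and counted in the
  summary's QC attribute.

Area fractions are area-weighted percentages over a region mask, with
the exposure bands: `TAWSS < 0.1 Pa` (below the physiological range),
`7 < WSS_max ≤ 40 Pa` (above it; half-open band), `WSS_max > 40 Pa`
(endothelial damage level) and `OSI > 0.25` (highly oscillatory). Band
and exceedance are disjoint by construction. The venous perianastomotic
mask selects surface points whose vein arc-length coordinate lies in
[−2.5 cm, +3.0 cm] around the venous anastomosis (distal negative,
closed interval); surface vertices carry their branch and arc coordinate
from the sweep precisely so this projection is trivial and exact.
Vertex area weights take one third of each adjacent triangle.

Transitional flow is quantified by Reynolds decomposition of the
velocity magnitude into a slow trend and high-frequency perturbations.
The trend is a zero-phase FFT brick-wall low-pass over the periodic
cycle (exact for periodic signals, no IIR edge transients) with a 15 Hz
default cutoff — cardiac harmonics stay in the trend, transitional
oscillations at several tens of Hz land wholly in the perturbation band.
`ũ_RMS` is the per-point perturbation RMS; `ũ_RMS,50` collapses it to a
centerline profile by taking, at equally spaced stations, the median over
the points within half a station spacing — the median deliberately
resists the few extreme values inside a jet core. Stations without
points are reported missing rather than interpolated.

## Synthetic fixtures and what passing tests mean

Every generator records its ground truth next to the data: WSS patterns
with closed-form TAWSS/WSS_max/OSI (constant; zero-mean sinusoid, OSI
exactly 0.5; a ¾/¼ reversing pattern, OSI exactly 0.25; a two-level
field holding a prescribed area fraction above 7 Pa), velocity fields
with exact per-point perturbation RMS (band-limited noise rescaled per
point, or a pure sinusoid in the 35–45 Hz band), waveforms with exact
mean and PI, and warped centerline trees with exact junction
coordinates. All stochastic generators are seed-deterministic and leave
the caller's RNG stream untouched.

Passing this suite demonstrates that the implementations compute their
definitions correctly and that the surrogate reproduces the qualitative
boundary-condition physics. It does not validate the surrogate against
3D CFD or clinical measurements: synthetic fields contain no jet
impingement, no wall curvature effects, and no turbulence spectrum
beyond what is injected.

## Problem sizes and runtime

Default sizes were chosen so the whole suite runs comfortably on one
CPU: loop runs use 3 cycles × 10⁴ steps; fixtures use a few hundred
points and 64–512 time samples; surfaces a few thousand faces. The full
test suite completes in well under a minute; `scripts/acceptance.R` in a
few seconds.

## Known limitations

Rigid vessels (no graft–vein compliance mismatch); constant-diameter
circular lumina; no stenosis; non-conformal surface junctions; a linear
loop surrogate (no minor losses, no convective effects); the clinical
inlet morphology is a documented stand-in, not a measured trace; and the
collateral controller's smoothing assumes a strictly periodic cardiac
cycle.
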