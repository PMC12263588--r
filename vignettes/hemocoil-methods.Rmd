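---
title: "Methods: Windkessel calibration, 0D outlet networks, virtual coiling and wall shear indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Windkessel calibration, 0D outlet networks, virtual coiling and wall shear indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemocoil)
```

hemocoil models the hemodynamic consequences of stent-graft exclusion and
adjunctive coil embolization of aortic arch aneurysms at "desk scale": the
boundary-condition calibration, the outlet network dynamics, the coil
geometry and the wall-shear post-processing of a patient-specific CFD
study, with the 3D flow solve itself deliberately out of scope. This
vignette explains each model, its assumptions, the tunable parameters, and
the design choices made where the methodology was genuinely open.

All internal units are SI (Pa, m, s, m³/s). Clinical pressures enter in
mmHg through `mmHg_to_pa()` (1 mmHg = 133.322 Pa).

## Three-element Windkessel calibration

Each outflow branch of the arch — brachiocephalic trunk (BT), left common
carotid (LCC), left subclavian artery (LSA) and descending aorta (DA) —
is closed by a three-element Windkessel: proximal (characteristic)
resistance $R_1$, distal resistance $R_2$ and compliance $C$, terminating
at the capillary pressure $P_{out} = 4426$ Pa.

The calibration chain is:

* Mean pressure from cuff extrema, $P_m = P_d + (P_s - P_d)/3$. This is
  the standard clinical estimate of the time-averaged arterial pressure.
* Total resistance $R_{total} = (P_m - P_{out})/\bar Q_{in}$, with
  $\bar Q_{in}$ the mean inflow. When no measured mean flow is supplied,
  it is computed as the time average of the inflow waveform — never
  defaulted silently.
* Parallel split by cross-sectional area,
  $R_{total,i} = (A_{total}/A_i)\,R_{total}$, which conserves the
  parallel combination exactly.
* Characteristic impedance $R_{1,i} = \rho_f c_{di}/A_{di}$, with the
  empirical wave speed $c_{di} = \xi D_{di}^{-1/2}$, $\xi = 0.72$, $D$ in
  metres. The coefficient's conventional printed unit is dimensionally
  loose; applied numerically in SI it yields physiological wave speeds
  (≈ 5 m/s at a 2 cm diameter) and branch impedances of the magnitudes
  seen in published per-outlet tables, so it is used as an empirical
  relation and documented as such.
* Distal remainder $R_{2,i} = R_{total,i} - R_{1,i}$. If a branch is so
  narrow that its characteristic impedance exceeds its total share, the
  calibration fails loudly, naming the outlet.
* Global compliance $C_T = (Q_{max}-Q_{min})/(P_s-P_d)\cdot\Delta t$,
  where $\Delta t$ is the interval between the inflow extrema. How $C_T$
  should be split over outlets is not fixed by the formulation; hemocoil
  distributes it in proportion to $1/R_{total,i}$ (equivalently to branch
  area), the standard peripheral-bed practice, normalised so the parts
  sum to $C_T$ exactly.

The packaged per-outlet boundary-condition table (`windkessel_table()`) is
shipped as a verbatim fixture for reference and testing. It is *not* used
as calibration ground truth: its implied time constants $R_2 C$ reach
hundreds of seconds, which is incompatible with periodic convergence in a
handful of cardiac cycles, so recovering those exact values is not a
meaningful target for this calibration chain.

## The 0D outlet network

The 3D momentum/continuity solve of a full CFD study is replaced by a
single-junction 0D surrogate: the inlet-node pressure is prescribed by the
waveform, and each outlet obeys

$$Q_i = \frac{P_{in} - P_{c,i}}{R_{1,i}}, \qquad
  C_i \frac{dP_{c,i}}{dt} = Q_i - \frac{P_{c,i} - P_{out}}{R_{2,i}}.$$

This is the level at which such a study's own validation operates
(simulated inlet pressures against cuff pressures; outlet flow waveforms),
which is why the surrogate is a faithful test bed for the boundary-value
machinery even though it cannot reproduce 3D flow fields.

Numerical choices:

* **Integrator.** Implicit first-order (backward Euler) update per step,
  at the reference stepping of Δt = 0.01 s with 84 steps per 0.84 s
  cycle. Backward Euler is unconditionally stable, which matters because
  calibrated and published $R_2C$ products span milliseconds to minutes.
  The price is first-order accuracy: halving the step changes
  pulse-driven final-cycle flows by about 1.5% at the reference step, and
  single-harmonic amplitudes carry an $\mathcal{O}(\omega\Delta t/2)$
  damping error (~3% at Δt = 0.01 s). Tests of the frequency-domain
  equivalence against the closed-form impedance
  $Z(\omega) = R_1 + R_2/(1 + j\omega R_2 C)$ therefore run at
  Δt = 0.001 s, where agreement is within 1%; at the reference step the
  refinement sequence is verified to converge first order.
* **Initialisation.** Compliance-node pressures start at their
  quasi-steady value for the $t=0$ inlet pressure (configurable to any
  fixed pressure). Starting at $P_{out}$ injects an artificial start-up
  transient that the cycle-to-cycle metric would attribute to the
  physics; the quasi-steady start makes the reported convergence cycle
  reflect the outlet time constants. With steady forcing it reproduces
  the exact steady state, so steady runs converge at the first comparable
  cycle.
* **Convergence metric.** Cycle $k$ is converged when
  $\max_{i,t} |Q^{(k)} - Q^{(k-1)}| / \max |Q^{(k)}| < 1\%$ (tolerance
  configurable). The max-norm includes every sample, so a transient that
  dies *within* cycle 1 is still visible in the cycle-2 comparison; the
  practical bound is the exponential-decay estimate
  $\lceil \tau \ln(1/\mathrm{tol})/T \rceil$ plus the two comparison
  cycles.
* **Junction balance.** Total inlet flow is defined as $\sum_i Q_i$ at
  the single junction, so mass conservation holds identically at every
  step; the test suite instead checks the internal consistency
  $Q_i = (P_{in}-P_{c,i})/R_{1,i}$ of the stored traces.
* Mass flow is reported in kg/s using $\rho_f = 1060$ kg/m³ alongside
  volumetric flow.

A note on flow positivity: with $P_{in}(t) \ge P_{out}$, outlet flows
remain non-negative when $R_1$ is a material fraction of the branch total.
When $R_1$ is nearly zero the compliance node tracks the inlet so closely
that a fast-falling pressure transiently drops below it — diastolic
backflow, which is physical, not a solver artifact.

## Synthetic anatomy and waveforms

`make_sac()` builds watertight sphere/ellipsoid sacs by icosahedral
subdivision; mesh volume converges to the analytic solid volume from
below as resolution refines (within 1% at the default subdivision floor),
and each sac carries an analytic signed-distance closure used for coil
containment. The ellipsoid signed distance uses the scaled-space estimate,
exact in sign and near-exact in magnitude for the mild eccentricities
generated here.

`make_outlet_set()` derives the four branch areas by inverting the
parallel-resistance split against the packaged per-outlet table (area
proportional to one over the branch's total resistance), so a subsequent
calibration orders branch resistances like the reference data, with DA
the largest branch. Areas sum exactly to the requested total; diastolic
diameters assume a circular lumen.

`make_waveform()` synthesises one cardiac cycle with exact sampled
extrema. The measured clinical waveform is not tabulated anywhere
reusable, so the `two_phase_pulse` shape — systolic rise and fall to a
dicrotic notch, then exponential diastolic relaxation — stands in for it;
only the extrema, the period and the cycle mean enter any downstream
formula. The cardiac period defaults to 0.84 s, the value implied by a
0.01 s step with 84 steps per cycle, and is configurable. One deliberate
calibration is applied to the shape: its normalised samples are warped by
a solved exponent so the cycle mean sits exactly one third of the pulse
height above the minimum. That makes the synthetic pressure wave
consistent with the cuff estimate $P_m = P_d + (P_s-P_d)/3$ used by the
calibration, which is what allows calibrate → simulate → re-measure to
recover $P_m$ to within discretisation error rather than inheriting a
several-percent bias from an arbitrary pulse shape.

`make_wss_field()` plants ground truth for the index stage: nodes are
ranked deterministically and labelled "low shear" until their cumulative
barycentric area reaches the requested fraction (achievable only to
one-triangle granularity on a fixed mesh, which is the tolerance all
round-trip tests use). Steady nodes hold a constant vector (OSI exactly
0); reversing nodes follow a single zero-mean harmonic (OSI exactly 0.5),
with amplitudes scaled by $\pi/2$ so the time-averaged magnitude equals
the target TAWSS. What passing these round-trips shows is that the index
pipeline is correct, not that real post-TEVAR shear fields look like
this: real fields are spatially correlated, multi-harmonic and tangent to
the wall, none of which the generator emulates.

## Virtual coil embolization

Coils are generated as seeded constrained random walks of circular loops
confined to the sac (`generate_coil()`), mirroring the device family used
clinically: 0.6 mm wire, 18 mm loop diameter, lengths 40/80/160 cm.

* `planar2D` stacks loops along one fixed axis at a pitch of 1.2 wire
  diameters with small lateral jitter; a loop's plane-fit residual stays
  below the wire diameter, matching the "stack of parallel planes"
  reading of 2D deployment. Whether clinical "2D" coils occupy one plane
  or several is not observable from biplanar projections; the stacked
  interpretation is the configurable default.
* `helical3D` precesses the loop axis by a random tilt per turn (biased
  back toward the sac centroid when the walk drifts outward), producing
  spiral winding with varying loop axes. The turn-to-turn pitch grows
  with the maximum precession angle so tilted neighbouring loops cannot
  touch.
* **Constraints.** Every point must sit at least half a wire diameter
  inside the sac (signed distance), and every segment at least one wire
  diameter from all non-adjacent segments (centerline-to-centerline, i.e.
  wire surfaces may just touch). Segments within two indices are
  exempt so curvature itself is not flagged. A candidate loop violating
  either constraint is redrawn; after a bounded retreat budget (1000 by
  default) generation fails explicitly, reporting the achieved length.
* **Length.** The wire is trimmed by interpolating the final point, so
  the polyline arc length equals the specified length to machine
  precision. The loop radius never exceeds the specification and adapts
  downward in small sacs.
* The "overall diameter" of the reference device is read as the loop
  diameter (matching device nomenclature), not the deployed-mass
  envelope.

`check_constraints()` is an independent verifier: exact all-pairs
segment-segment minimum distance (interior solution when valid, endpoint
cases otherwise) with no spatial index shared with the generator, plus a
wall-margin scan on a densified polyline. `sweep_tube()` exports a
watertight tube mesh with parallel-transported frames; ring vertices sit
at the circumscribed-polygon radius so the polygon's inscribed circle
matches the wire surface, and `measure_tube_diameter()` applies the
matching $\cos(\pi/\text{sides})$ correction when measuring it back.

Packing density is the cylinder wire volume over the sac volume. The
mechanics of deployment (radial forces, friction, wall compliance) are
out of scope, as they are in the virtual-coiling protocol this mirrors.

## Wall shear indices

The index definitions are the standard literature forms (the source
protocol names the thresholds but not the formulas):

$$\mathrm{TAWSS} = \frac{1}{T}\int_0^T |\boldsymbol\tau|\,dt,\qquad
\mathrm{OSI} = \frac12\left(1 - \frac{|\int_0^T \boldsymbol\tau\,dt|}{\int_0^T |\boldsymbol\tau|\,dt}\right),\qquad
\mathrm{RRT} = \frac{1}{(1-2\,\mathrm{OSI})\,\mathrm{TAWSS}}.$$

Time integrals use the trapezoid rule on the field's sample grid, which
must span exactly one period. Node area weights are barycentric (one
third of incident triangle areas). Degenerate nodes with vanishing
$\int|\tau|\,dt$ get OSI 0 and are counted, not dropped; RRT is flagged
infinite where OSI reaches 0.5 or TAWSS vanishes, with an optional cap.
Area fractions count nodes strictly beyond the threshold (ties excluded).
Thresholds default to TAWSS < 0.4 Pa, OSI > 0.4, RRT > 10 Pa⁻¹ and are
configurable. Whether clinical area fractions are quoted over the whole
lumen or the sac patch alone is ambiguous in practice; the functions
operate on whatever surface (and hence patch) they are given.

## Pipeline and problem sizes

`run_experiment()` chains the stages from one configuration with a single
seed, writing per-stage CSV/STL/JSON artifacts and a consolidated
summary; stages communicate only through these declared files. The 3D
coupling between coil packing and sac hemodynamics cannot exist at 0D, so
the pipeline uses a declared synthetic mapping — planted low-shear area
fraction rising linearly with packing density — visible in the
configuration and labelled synthetic; it exercises the index stage end to
end and supports monotonicity checks, nothing more.

Default problem sizes were chosen so a full test run and the acceptance
script complete in minutes on one CPU: sacs at icosphere subdivision 3–4
(642–2562 vertices), four 84-step cardiac cycles (840 steps for the
frequency-domain oracle), coils sampled at 48 points per turn (≈ 1360
points for the 160 cm coil), and wall-shear fields with 33 time samples.
Each of these is a function argument, not a limit.

## Known limitations

* No 3D or 1D wave propagation: stent grafts and coils influence nothing
  upstream of the declared synthetic coupling.
* The empirical wave-speed coefficient is applied numerically in SI; its
  dimensional status is inherited, not resolved.
* The compliance split across outlets is a convention, not a measurement.
* Coil generation validates geometric constraints only; it does not model
  deployment mechanics, and very aggressive packing (lengths far beyond
  the sac's stacking capacity) ends in an explicit packing failure rather
  than a denser configuration.
* Synthetic wall-shear fields are not tangent to the surface and carry no
  spatial correlation structure.
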