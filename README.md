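# hemocoil

Desk-scale hemodynamic modelling of stent-grafted, coil-embolized aortic
arch aneurysms, for researchers in cardiovascular biomechanics who need the
boundary-condition and post-processing machinery of a patient-specific CFD
study without the patient data or the 3D solver. The package covers four
stages as composable R functions:

1. **Windkessel calibration** — per-outlet three-element (RCR) boundary
   conditions from cuff pressures, mean inflow and outlet anatomy:

   - mean pressure: `Pm = Pd + (Ps − Pd)/3`
   - total resistance: `R_total = (Pm − Pout)/Q̄in`, `Pout = 4426 Pa`
   - parallel area split: `R_total,i = (A_total/A_i)·R_total`
   - characteristic impedance: `R1,i = ρf·c_di/A_di`, `c_di = ξ·D_di^(−1/2)`
     with `ρf = 1060 kg/m³`, `ξ = 0.72`
   - distal remainder: `R2,i = R_total,i − R1,i`
   - global compliance: `C_T = (Qmax − Qmin)/(Ps − Pd)·Δt`, distributed
     over outlets in proportion to `1/R_total,i`
2. **0D lumped network** — a prescribed inlet pressure wave driving four
   RCR outlets (`Q_i = (P_in − Pc_i)/R1_i`,
   `C_i dPc_i/dt = Q_i − (Pc_i − Pout)/R2_i`), integrated implicitly at
   Δt = 0.01 s, 84 steps per 0.84 s cardiac cycle, with cycle-to-cycle
   convergence reporting and a closed-form impedance oracle
   `Z(ω) = R1 + R2/(1 + jωR2C)`.
3. **Virtual coil embolization** — seeded constrained construction of
   0.6 mm-wire, 18 mm-loop coil centerlines (planar-stacked or
   helical/precessing morphologies) inside a sac surface, with brute-force
   verification of non-overlap and containment, packing density, and a
   watertight swept-tube mesh export.
4. **Wall shear indices** — TAWSS, OSI and RRT maps from time-resolved
   wall-shear vector fields, with area fractions beyond the standard
   thresholds (TAWSS < 0.4 Pa, OSI > 0.4, RRT > 10 Pa⁻¹).

A synthetic-anatomy module (`make_sac()`, `make_outlet_set()`,
`make_waveform()`, `make_wss_field()`) generates every input with known
ground truth, so the full pipeline runs and is tested without any imaging
data. The per-outlet boundary-condition table of the reference study ships
as a verbatim fixture (`windkessel_table()`).

## Worked example

```r
library(hemocoil)

inflow  <- make_waveform("flow", 4.2e-4, -0.3e-4)        # m^3/s
patient <- patient_hemodynamics(mmHg_to_pa(117), mmHg_to_pa(82),
                                inflow, mean_inflow = 1e-4)
params  <- calibrate_windkessel(patient, make_outlet_set("patient1_like"))
params
#> <windkessel_params>
#>   outlet        R1        R2         C
#> 1     BT  43478912 388057799 2.342e-09
#> 2    LCC 120506918 854941698 1.036e-09
#> 3    LSA  99064853 734866868 1.212e-09
#> 4     DA   9441778 117743788 7.947e-09
#> Pm = 12487.8 Pa, R_total = 8.062e+07 Pa s/m^3, C_T = 1.254e-08 m^3/Pa
```

`R1 + R2` recombine in parallel to `R_total`; the DA branch, with the
largest area, takes the smallest resistance and the largest compliance
share. Feeding the parameters back through the 0D solver recovers the mean
pressure the calibration targeted:

```r
inlet <- make_waveform("pressure", mmHg_to_pa(117), mmHg_to_pa(82))
state <- simulate_network(inlet, params)
state
#> <network_state> 4 outlets, 336 steps (4 cycles), converged at cycle 3
```

Virtual coiling and shear analysis on a synthetic sac:

```r
sac  <- make_sac("sphere", 0.02, resolution = 0.004)   # 20 mm radius
coil <- generate_coil(coil_spec(total_length = 0.4, seed = 42L), sac)
coil
#> <coil_centerline> planar2D, 0.4000 m over 341 points (8 turns), loop 18.0 mm
packing_density(coil$spec, sac)
#> [1] 0.003402996

field <- make_wss_field(sac, "mixed", low_area_fraction = 0.10)
maps  <- wall_index_maps(field)
threshold_report(maps)$low_tawss
#> <area_fraction> below 0.4: 0.0996 (0.0004958 of 0.004978 m^2)
```

The whole chain is also available as a config-driven run
(`run_experiment()`, or the `inst/exec/hemocoil` script with
`run`/`compare`/`fixtures` subcommands) producing per-stage CSV/STL/JSON
outputs and a consolidated `summary.json`.

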