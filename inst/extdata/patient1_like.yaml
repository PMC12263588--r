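# Example experiment configuration: patient1-like synthetic anatomy with
# the 40/80/160 cm planar coil series. Pressures in mmHg, everything else
# SI. The `coupling` block is the declared synthetic mapping from coil
# packing density to the planted low-shear area fraction of the generated
# wall-shear field.
patient:
  systolic_mmHg: 117
  diastolic_mmHg: 82
  capillary_pa: 4426
  mean_inflow_m3s: 1.0e-4
  inflow:
    qmax: 4.2e-4
    qmin: -0.3e-4
outlets:
  template: patient1_like
  total_area: 8.0e-4
sac:
  shape: sphere
  dimensions: 0.02
  resolution: 0.004
waveform:
  period: 0.84
  n_samples: 84
  shape: two_phase_pulse
coils:
  - total_length: 0.4
    morphology: planar2D
  - total_length: 0.8
    morphology: planar2D
  - total_length: 1.6
    morphology: planar2D
coil_defaults:
  wire_diameter: 6.0e-4
  loop_diameter: 1.8e-2
settings:
  time_step: 0.01
  steps_per_cycle: 84
  n_cycles: 4
  convergence_tolerance: 0.01
thresholds:
  tawss: 0.4
  osi: 0.4
  rrt: 10
coupling:
  kind: synthetic_linear
  base_low_fraction: 0.02
  low_fraction_per_density: 0.5
  pattern: mixed
  n_times: 33
seed: 42
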