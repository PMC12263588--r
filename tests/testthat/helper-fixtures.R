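# Shared fixtures, built in code at test time.

# 20 mm-radius spherical sac used by the coil tests
test_sac <- function(radius = 0.02, resolution = 0.004) {
  make_sac("sphere", radius, resolution = resolution)
}

# single-outlet parameter table for the 0D solver
single_outlet_params <- function(r1 = 1e7, r2 = 1e8, c = 1e-9,
                                 name = "X") {
  p <- data.frame(outlet = name, R1 = r1, R2 = r2, C = c,
                  stringsAsFactors = FALSE)
  class(p) <- c("windkessel_params", "data.frame")
  p
}

# Windkessel table restricted to one patient, as solver-ready params
table1_params <- function(patient = "Patient-1") {
  tab <- windkessel_table(patient)
  p <- data.frame(outlet = tab$outlet, R1 = tab$R1, R2 = tab$R2,
                  C = tab$C, stringsAsFactors = FALSE)
  class(p) <- c("windkessel_params", "data.frame")
  p
}

# synthetic patient record matching the 117/82 mmHg study conditions
test_patient <- function() {
  inflow <- make_waveform("flow", 4.2e-4, -0.3e-4)
  patient_hemodynamics(mmHg_to_pa(117), mmHg_to_pa(82), inflow,
                       mean_inflow = 1e-4)
}

# hand-built waveform object for closed-form compliance checks
raw_flow_waveform <- function(qmax, qmin, extrema_interval, period = 0.84) {
  structure(list(times = c(0, period / 2), values = c(qmax, qmin),
                 period = period, kind = "flow", qmax = qmax, qmin = qmin,
                 extrema_interval = extrema_interval, shape = "sampled"),
            class = "inlet_waveform")
}

# single-node WSS field with prescribed per-time vectors (rows = times)
single_node_field <- function(vectors, period = 1) {
  n_t <- nrow(vectors)
  mesh <- list(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
               faces = matrix(c(1L, 2L, 3L), 1))
  vec <- array(0, dim = c(3, n_t, 3))
  for (node in 1:3) vec[node, , ] <- vectors
  structure(list(surface = mesh,
                 times = seq(0, period, length.out = n_t),
                 vectors = vec, period = period, pattern = "custom",
                 low_nodes = rep(FALSE, 3)),
            class = "wss_field")
}
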