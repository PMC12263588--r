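# Transient 0D surrogate of the outlet boundary model: a prescribed inlet
# pressure waveform drives four 3-element Windkessel outlets attached to a
# single junction. Per outlet, with compliance-node pressure Pc:
#   Q_i = (P_in - Pc_i) / R1_i
#   C_i dPc_i/dt = Q_i - (Pc_i - Pout) / R2_i
# integrated with an implicit (backward) first-order update per step, which
# is unconditionally stable for the stiff R2*C time constants that occur in
# calibrated parameter sets.

#' Transient solver settings
#'
#' @param time_step solver step (s); the default 0.01 s with 84 steps per
#'   cycle matches a 0.84 s cardiac period.
#' @param steps_per_cycle steps per cardiac cycle.
#' @param n_cycles cycles to integrate.
#' @param convergence_tolerance relative cycle-to-cycle flow-change
#'   tolerance declaring periodicity.
#' @param pout capillary pressure (Pa) closing each outlet.
#' @param initial_compliance_pressure starting compliance-node pressure
#'   (Pa). The default `NULL` initializes each node at its quasi-steady
#'   value for the inlet pressure at t = 0, which removes the artificial
#'   start-up transient for fast outlets; a number forces that pressure.
#' @param blood_density kg/m^3, used only to report mass flow.
#' @return a `simulation_settings` list.
#' @export
simulation_settings <- function(time_step = 0.01, steps_per_cycle = 84,
                                n_cycles = 4, convergence_tolerance = 0.01,
                                pout = POUT_DEFAULT,
                                initial_compliance_pressure = NULL,
                                blood_density = 1060) {
  stopifnot(time_step > 0, steps_per_cycle >= 2, n_cycles >= 1,
            convergence_tolerance > 0)
  structure(list(time_step = time_step,
                 steps_per_cycle = as.integer(steps_per_cycle),
                 n_cycles = as.integer(n_cycles),
                 convergence_tolerance = convergence_tolerance,
                 pout = pout,
                 initial_compliance_pressure = initial_compliance_pressure,
                 blood_density = blood_density),
            class = "simulation_settings")
}

#' Complex impedance of a 3-element Windkessel outlet
#'
#' Z(omega) = R1 + R2 / (1 + j omega R2 C): the closed-form frequency
#' response of the RCR element, used as an independent oracle for the
#' transient solver.
#'
#' @param omega angular frequency (rad/s), >= 0.
#' @param r1,r2,c element parameters (Pa s/m^3, Pa s/m^3, m^3/Pa).
#' @return complex impedance (Pa s/m^3).
#' @examples
#' Mod(outlet_impedance(0, 1e7, 1e8, 1e-9))        # DC limit R1 + R2
#' @export
outlet_impedance <- function(omega, r1, r2, c) {
  if (any(omega < 0)) stop("omega must be non-negative")
  r1 + r2 / (1 + 1i * omega * r2 * c)
}

#' Integrate the 0D outlet network over several cardiac cycles
#'
#' The inlet-node pressure is prescribed by `inlet`; each outlet is a
#' 3-element Windkessel closed at the capillary pressure. The implicit
#' update per step is
#' \deqn{Pc^{n+1} = \frac{Pc^n + (\Delta t/C)(P_{in}^{n+1}/R_1 + P_{out}/R_2)}
#'   {1 + (\Delta t/C)(1/R_1 + 1/R_2)}}
#' with outlet flow evaluated at the new level, so the junction balance
#' (total inlet flow = sum of outlet flows) holds identically.
#'
#' @param inlet an `inlet_waveform` of kind `"pressure"`.
#' @param params a `windkessel_params` data.frame (`outlet`, `R1`, `R2`,
#'   `C`).
#' @param settings a [simulation_settings()] list; its
#'   `time_step * steps_per_cycle` must equal the waveform period.
#' @return a `network_state`: `times` (s), `inlet_pressure` (Pa), `Q`
#'   (time x outlet volumetric flows, m^3/s), `Q_mass` (kg/s), `Pc`
#'   (compliance-node pressures, Pa), `cycles_to_convergence`, `converged`,
#'   and per-cycle change metrics.
#' @export
simulate_network <- function(inlet, params,
                             settings = simulation_settings()) {
  if (!inherits(inlet, "inlet_waveform") || inlet$kind != "pressure") {
    stop("simulate_network needs a pressure inlet waveform")
  }
  s <- settings
  if (abs(s$time_step * s$steps_per_cycle - inlet$period) >
      1e-9 * inlet$period) {
    stop("time_step * steps_per_cycle must equal the waveform period")
  }
  if (any(params$R1 <= 0) || any(params$R2 <= 0) || any(params$C <= 0)) {
    stop("Windkessel parameters must be positive")
  }
  n_out <- nrow(params)
  nt <- s$n_cycles * s$steps_per_cycle + 1L
  times <- (seq_len(nt) - 1) * s$time_step
  p_in <- waveform_value(inlet, times)
  r1 <- params$R1; r2 <- params$R2; cc <- params$C
  a <- s$time_step / cc                 # dt / C_i
  denom <- 1 + a * (1 / r1 + 1 / r2)
  pc <- matrix(0, nt, n_out)
  q <- matrix(0, nt, n_out)
  pc[1, ] <- if (is.null(s$initial_compliance_pressure)) {
    # quasi-steady node pressure for the t = 0 inlet value
    (p_in[1] / r1 + s$pout / r2) / (1 / r1 + 1 / r2)
  } else {
    s$initial_compliance_pressure
  }
  q[1, ] <- (p_in[1] - pc[1, ]) / r1
  for (k in 2:nt) {
    pc[k, ] <- (pc[k - 1, ] + a * (p_in[k] / r1 + s$pout / r2)) / denom
    q[k, ] <- (p_in[k] - pc[k, ]) / r1
  }
  colnames(q) <- colnames(pc) <- params$outlet
  state <- structure(list(times = times, inlet_pressure = p_in, Q = q,
                          Q_mass = q * s$blood_density, Pc = pc,
                          settings = s, outlet_names = params$outlet),
                     class = "network_state")
  conv <- cycles_to_convergence(state, s$convergence_tolerance)
  state$cycles_to_convergence <- conv$cycle
  state$converged <- conv$converged
  state$cycle_change <- conv$metrics
  state
}

#' Cycle count to periodic convergence
#'
#' For each cycle k >= 2 computes the maximum (over outlets and time)
#' relative change of the flow traces against the previous cycle,
#' normalised by the cycle's peak flow magnitude, and returns the first
#' cycle meeting the tolerance. If the tolerance is never met the reported
#' cycle is `n_cycles + 1` with `converged = FALSE`.
#'
#' @param state a `network_state`.
#' @param tolerance relative tolerance; defaults to the state's setting.
#' @return list with `cycle`, `converged` and the per-cycle `metrics`.
#' @export
cycles_to_convergence <- function(state,
                                  tolerance =
                                    state$settings$convergence_tolerance) {
  s <- state$settings
  if (s$n_cycles < 2) stop("need at least 2 simulated cycles")
  sp <- s$steps_per_cycle
  metrics <- rep(NA_real_, s$n_cycles)
  for (k in 2:s$n_cycles) {
    idx_k <- ((k - 1) * sp + 2):(k * sp + 1)
    idx_prev <- idx_k - sp
    qk <- state$Q[idx_k, , drop = FALSE]
    scale <- max(abs(qk))
    if (scale == 0) scale <- 1
    metrics[k] <- max(abs(qk - state$Q[idx_prev, , drop = FALSE])) / scale
  }
  hit <- which(metrics < tolerance)
  if (length(hit)) {
    list(cycle = as.integer(hit[1]), converged = TRUE, metrics = metrics)
  } else {
    list(cycle = as.integer(s$n_cycles) + 1L, converged = FALSE,
         metrics = metrics)
  }
}

#' Compare simulated inlet-node pressure extrema with measurements
#'
#' Relative errors of the final cycle's inlet-node maximum and minimum
#' against measured systolic and diastolic pressures.
#'
#' @param state a `network_state`.
#' @param ps,pd measured systolic / diastolic pressure (Pa).
#' @return named vector `c(systolic = , diastolic = )` of relative errors.
#' @export
validate_pressures <- function(state, ps, pd) {
  s <- state$settings
  idx <- ((s$n_cycles - 1) * s$steps_per_cycle + 1):length(state$times)
  p <- state$inlet_pressure[idx]
  c(systolic = abs(max(p) - ps) / ps, diastolic = abs(min(p) - pd) / pd)
}

#' Final-cycle traces of a simulation
#'
#' @param state a `network_state`.
#' @return list with `times` (relative to cycle start), `inlet_pressure`,
#'   `Q`, `Pc` restricted to the last simulated cycle.
#' @export
final_cycle <- function(state) {
  s <- state$settings
  idx <- ((s$n_cycles - 1) * s$steps_per_cycle + 1):length(state$times)
  list(times = state$times[idx] - state$times[idx[1]],
       inlet_pressure = state$inlet_pressure[idx],
       Q = state$Q[idx, , drop = FALSE],
       Pc = state$Pc[idx, , drop = FALSE])
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf("<network_state> %d outlets, %d steps (%d cycles), %s at cycle %s\n",
              ncol(x$Q), length(x$times) - 1, x$settings$n_cycles,
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$cycles_to_convergence))
  invisible(x)
}

#' Write flow traces as CSV
#'
#' Columns: time (s), inlet pressure (Pa), then one mass-flow column per
#' outlet (kg/s).
#'
#' @param state a `network_state`.
#' @param path CSV path.
#' @export
write_traces_csv <- function(state, path) {
  df <- data.frame(time = state$times, P_in = state$inlet_pressure)
  qm <- as.data.frame(state$Q_mass)
  names(qm) <- paste0("Q_", state$outlet_names)
  utils::write.csv(cbind(df, qm), path, row.names = FALSE)
  invisible(path)
}
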