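# Three-element Windkessel (RCR) outlet calibration: from patient-style
# pressures, mean inflow and outlet anatomy to per-outlet (R1, R2, C).
# All quantities SI: Pa, m, s, m^3/s, Pa s/m^3, m^3/Pa.

#' Patient hemodynamic record
#'
#' Bundles the measured quantities driving the calibration: systolic and
#' diastolic cuff pressures, mean arterial inflow and the capillary
#' (outflow reference) pressure, plus the inflow waveform used for the
#' compliance estimate. When `mean_inflow` is omitted it is computed as the
#' time average of the supplied inflow waveform; it is never defaulted
#' silently.
#'
#' @param systolic_pressure,diastolic_pressure Pa.
#' @param inflow_waveform an `inlet_waveform` of kind `"flow"` (m^3/s).
#' @param mean_inflow mean inflow (m^3/s); default: time average of
#'   `inflow_waveform`.
#' @param capillary_pressure outflow reference pressure Pout (Pa).
#' @return a `patient_hemodynamics` object.
#' @export
patient_hemodynamics <- function(systolic_pressure, diastolic_pressure,
                                 inflow_waveform, mean_inflow = NULL,
                                 capillary_pressure = POUT_DEFAULT) {
  if (!inherits(inflow_waveform, "inlet_waveform") ||
      inflow_waveform$kind != "flow") {
    stop("inflow_waveform must be an inlet_waveform of kind 'flow'")
  }
  if (is.null(mean_inflow)) mean_inflow <- waveform_mean(inflow_waveform)
  if (!(systolic_pressure > diastolic_pressure &&
        diastolic_pressure > capillary_pressure && capillary_pressure >= 0)) {
    stop("need Ps > Pd > Pout >= 0")
  }
  if (mean_inflow <= 0) stop("mean inflow must be positive")
  structure(list(systolic_pressure = systolic_pressure,
                 diastolic_pressure = diastolic_pressure,
                 mean_inflow = mean_inflow,
                 capillary_pressure = capillary_pressure,
                 inflow_waveform = inflow_waveform),
            class = "patient_hemodynamics")
}

#' Mean arterial pressure from cuff extrema
#'
#' Pm = Pd + (Ps - Pd)/3, the standard cuff estimate of mean pressure.
#'
#' @param ps,pd systolic and diastolic pressure (any single pressure unit).
#' @return mean pressure in the same unit.
#' @examples
#' pa_to_mmhg(mean_pressure(mmHg_to_pa(117), mmHg_to_pa(82)))
#' @export
mean_pressure <- function(ps, pd) {
  if (any(ps < pd)) stop("systolic pressure must be >= diastolic")
  pd + (ps - pd) / 3
}

#' Total peripheral resistance
#'
#' R_total = (Pm - Pout) / Qin_bar: the lumped resistance of the whole
#' outlet network seen from the inlet.
#'
#' @param pm mean arterial pressure (Pa).
#' @param pout capillary pressure (Pa).
#' @param qin_bar mean inflow (m^3/s).
#' @return total resistance (Pa s/m^3).
#' @export
total_resistance <- function(pm, pout, qin_bar) {
  if (qin_bar <= 0) stop("mean inflow must be positive")
  if (pm < pout) stop("mean pressure below capillary pressure")
  (pm - pout) / qin_bar
}

#' Split total resistance across outlets by area
#'
#' Parallel-resistance principle: each outlet receives
#' R_total_i = (A_total / A_i) * R_total, so the parallel combination of
#' the branch resistances recovers R_total exactly.
#'
#' @param r_total total resistance (Pa s/m^3).
#' @param areas per-outlet cross-sectional areas (m^2), optionally named.
#' @param total_area override for the summed area; defaults to
#'   `sum(areas)`.
#' @return named vector of per-outlet total resistances.
#' @export
split_outlet_resistance <- function(r_total, areas, total_area = sum(areas)) {
  if (any(areas <= 0)) stop("outlet areas must be positive")
  (total_area / areas) * r_total
}

#' Proximal (characteristic) impedance of an outlet
#'
#' R1_i = rho_f * c_di / A_di with the wave speed from the empirical fit
#' c_di = xi * D_di^(-1/2) (D in m, c in m/s). This is the instantaneous
#' pressure-flow ratio at the branch entrance.
#'
#' @param d_di diastolic diameter (m).
#' @param a_di diastolic cross-sectional area (m^2); default pi d^2/4.
#' @param constants a [calibration_constants()] list.
#' @return proximal resistance (Pa s/m^3).
#' @export
proximal_resistance <- function(d_di, a_di = pi * d_di^2 / 4,
                                constants = calibration_constants()) {
  if (any(d_di <= 0) || any(a_di <= 0)) {
    stop("diameter and area must be positive")
  }
  c_di <- constants$wave_speed_coefficient * d_di^(-0.5)
  constants$blood_density * c_di / a_di
}

#' Distal resistance of an outlet
#'
#' R2_i = R_total_i - R1_i; errors when the characteristic impedance
#' already exceeds the branch's total resistance.
#'
#' @param r_total_i per-outlet total resistance.
#' @param r1_i per-outlet proximal resistance.
#' @param names optional outlet names for diagnostics.
#' @return distal resistances (Pa s/m^3).
#' @export
distal_resistance <- function(r_total_i, r1_i, names = NULL) {
  bad <- r1_i >= r_total_i
  if (any(bad)) {
    lab <- if (!is.null(names)) paste(names[bad], collapse = ", ")
           else paste(which(bad), collapse = ", ")
    stop("characteristic impedance exceeds total resistance at outlet(s): ",
         lab)
  }
  r_total_i - r1_i
}

#' Global arterial compliance from the inflow pulse
#'
#' C_T = (Qmax - Qmin) / (Ps - Pd) * dt, where dt is the interval between
#' the occurrences of the inflow extrema: the systemic energy-storage
#' (buffering) capacity.
#'
#' @param waveform an `inlet_waveform` of kind `"flow"`.
#' @param ps,pd systolic and diastolic pressures (Pa).
#' @return total compliance (m^3/Pa).
#' @export
total_compliance <- function(waveform, ps, pd) {
  if (!inherits(waveform, "inlet_waveform") || waveform$kind != "flow") {
    stop("total_compliance needs a flow waveform")
  }
  if (ps <= pd) stop("pulse pressure must be positive")
  (waveform$qmax - waveform$qmin) / (ps - pd) * waveform$extrema_interval
}

#' Distribute global compliance across outlets
#'
#' The per-outlet split is proportional to 1/R_total_i (equivalently to
#' outlet area), normalised so the parts sum to C_T — the standard
#' peripheral-bed apportioning.
#'
#' @param c_t global compliance (m^3/Pa).
#' @param r_total_i per-outlet total resistances.
#' @return per-outlet compliances summing to `c_t`.
#' @export
distribute_compliance <- function(c_t, r_total_i) {
  if (c_t < 0) stop("compliance must be non-negative")
  w <- (1 / r_total_i) / sum(1 / r_total_i)
  c_t * w
}

#' Calibrate per-outlet Windkessel parameters
#'
#' Runs the whole chain: mean pressure, total resistance, area-based
#' parallel split, characteristic impedance from diastolic geometry, distal
#' remainder, global compliance from the inflow pulse and its per-outlet
#' distribution.
#'
#' @param patient a [patient_hemodynamics()] record.
#' @param outlets an `outlet_set` (from [make_outlet_set()] or a
#'   data.frame with `name`, `area`, `diastolic_diameter`, optionally
#'   `diastolic_area`).
#' @param constants a [calibration_constants()] list.
#' @return a `windkessel_params` object: data.frame with `outlet`, `R1`,
#'   `R2`, `C`, plus a `report` attribute holding the intermediate values
#'   (`Pm`, `R_total`, `C_T`, per-outlet `R_total_i`).
#' @export
calibrate_windkessel <- function(patient, outlets,
                                 constants = calibration_constants()) {
  ps <- patient$systolic_pressure
  pd <- patient$diastolic_pressure
  pm <- mean_pressure(ps, pd)
  r_total <- total_resistance(pm, patient$capillary_pressure,
                              patient$mean_inflow)
  a_di <- if ("diastolic_area" %in% names(outlets)) outlets$diastolic_area
          else pi * outlets$diastolic_diameter^2 / 4
  r_tot_i <- split_outlet_resistance(r_total, outlets$area)
  r1 <- proximal_resistance(outlets$diastolic_diameter, a_di, constants)
  r2 <- distal_resistance(r_tot_i, r1, names = outlets$name)
  c_t <- total_compliance(patient$inflow_waveform, ps, pd)
  ci <- distribute_compliance(c_t, r_tot_i)
  params <- data.frame(outlet = outlets$name, R1 = r1, R2 = r2, C = ci,
                       stringsAsFactors = FALSE)
  attr(params, "report") <- list(Pm = pm, R_total = r_total, C_T = c_t,
                                 R_total_i = stats::setNames(r_tot_i,
                                                             outlets$name),
                                 Pout = patient$capillary_pressure,
                                 Q_in = patient$mean_inflow)
  class(params) <- c("windkessel_params", "data.frame")
  params
}

#' @export
print.windkessel_params <- function(x, ...) {
  cat("<windkessel_params>\n")
  print.data.frame(x, digits = 4)
  rep <- attr(x, "report")
  if (!is.null(rep)) {
    cat(sprintf("Pm = %.1f Pa, R_total = %.4g Pa s/m^3, C_T = %.4g m^3/Pa\n",
                rep$Pm, rep$R_total, rep$C_T))
  }
  invisible(x)
}

#' Write calibrated parameters as CSV (one outlet per row)
#' @param params a `windkessel_params` data.frame.
#' @param path CSV path.
#' @export
write_params_csv <- function(params, path) {
  utils::write.csv(as.data.frame(params), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_params_csv
#' @export
read_params_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(tab) <- c("windkessel_params", "data.frame")
  tab
}
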