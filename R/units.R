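#' Unit conversions and physical constants
#'
#' All internal quantities in hemocoil are SI (Pa, m, s, m^3/s). Clinical
#' pressures are usually quoted in mmHg; these helpers convert at the I/O
#' boundary using 1 mmHg = 133.322 Pa.
#'
#' @param x numeric vector of pressures.
#' @return numeric vector in the target unit.
#' @examples
#' mmHg_to_pa(117)
#' pa_to_mmhg(133.322)
#' @export
mmHg_to_pa <- function(x) x * 133.322

#' @rdname mmHg_to_pa
#' @export
pa_to_mmhg <- function(x) x / 133.322

#' Blood and wave-speed constants for Windkessel calibration
#'
#' Bundles the physical constants entering the outlet boundary-condition
#' calibration: blood density and viscosity for a Newtonian blood analogue
#' (hematocrit about 45%), and the empirical wave-speed coefficient used in
#' the characteristic (proximal) impedance, applied as
#' \eqn{c = \xi D^{-1/2}} with \eqn{D} in metres and \eqn{c} in m/s.
#'
#' The coefficient's conventional printed unit is dimensionally loose; it is
#' applied numerically in SI, which yields physiological wave speeds (about
#' 5 m/s at D = 2 cm).
#'
#' @param blood_density fluid density rho_f, kg/m^3.
#' @param blood_viscosity dynamic viscosity mu, Pa s.
#' @param wave_speed_coefficient xi in c = xi * D^(-1/2).
#' @return a list of class `calibration_constants`.
#' @export
calibration_constants <- function(blood_density = 1060,
                                  blood_viscosity = 3.5e-3,
                                  wave_speed_coefficient = 0.72) {
  stopifnot(blood_density > 0, blood_viscosity > 0,
            wave_speed_coefficient > 0)
  structure(list(blood_density = blood_density,
                 blood_viscosity = blood_viscosity,
                 wave_speed_coefficient = wave_speed_coefficient),
            class = "calibration_constants")
}

# Default capillary (outflow reference) pressure, Pa.
POUT_DEFAULT <- 4426
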