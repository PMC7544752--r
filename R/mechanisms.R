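# Analytic single-airway deposition mechanics: Brownian diffusion
# (Ingham-type series for laminar tube flow), gravitational sedimentation
# (inclined-tube formula) and inertial impaction (branching-angle Stokes
# formula), plus the empirical extrathoracic (nasal) efficiencies.

# Air properties at airway conditions
.AIR <- list(
  temperature_K = 310,        # body temperature
  viscosity = 1.90e-5,        # Pa s
  mean_free_path_m = 7.0e-8,  # m
  density = 1.13              # kg/m^3
)
.K_BOLTZMANN <- 1.380649e-23
.GRAVITY <- 9.81

#' Cunningham slip correction factor
#'
#' `Cc = 1 + Kn * (1.257 + 0.4 exp(-1.1 / Kn))` with Knudsen number
#' `Kn = 2 * mean free path / d`.
#'
#' @param d_nm particle diameter (nm).
#' @return dimensionless slip correction, vectorised over `d_nm`.
#' @export
cunningham_slip <- function(d_nm) {
  kn <- 2 * .AIR$mean_free_path_m / (d_nm * 1e-9)
  1 + kn * (1.257 + 0.4 * exp(-1.1 / kn))
}

#' Brownian diffusion coefficient of an aerosol particle
#'
#' Stokes-Einstein with slip correction, at airway temperature.
#'
#' @param d_nm particle diameter (nm).
#' @return diffusion coefficient (m^2/s).
#' @export
particle_diffusivity <- function(d_nm) {
  d <- d_nm * 1e-9
  .K_BOLTZMANN * .AIR$temperature_K * cunningham_slip(d_nm) /
    (3 * pi * .AIR$viscosity * d)
}

#' Gravitational settling velocity
#'
#' @param d_nm particle diameter (nm).
#' @param particle_density particle density (kg/m^3); the standard-density
#'   convention (1000) is used for the activity aerosol.
#' @return terminal settling velocity (m/s).
#' @export
settling_velocity <- function(d_nm, particle_density = 1000) {
  d <- d_nm * 1e-9
  particle_density * d^2 * .GRAVITY * cunningham_slip(d_nm) /
    (18 * .AIR$viscosity)
}

# Ingham series for diffusional deposition from laminar flow in a tube,
# as a function of the dimensionless deposition parameter
# delta = pi * D * L / (4 * Q).
.ingham_diffusion <- function(delta) {
  p <- 1 - 0.819 * exp(-14.63 * delta) - 0.0976 * exp(-89.22 * delta) -
    0.0325 * exp(-228 * delta) - 0.0509 * exp(-125.9 * delta^(2 / 3))
  pmin(pmax(p, 0), 1)
}

#' Combined deposition probability in a cylindrical airway
#'
#' Probability that a particle traversing one airway tube deposits, combined
#' from the three classical mechanisms as
#' `p = 1 - (1 - p_diff)(1 - p_sed)(1 - p_imp)`:
#' * diffusion: Ingham series in `delta = pi D L / (4 Q)`;
#' * sedimentation: inclined-tube formula
#'   `p_sed = 1 - exp(-(4 g_eps) / pi)` with
#'   `g_eps = 3 v_s L cos(phi) / (4 u d_t)` capped so the term stays in
#'   \[0, 1\] (v_s settling velocity, u mean flow speed, phi tube angle
#'   from vertical... measured here as the gravity angle, 0 = horizontal
#'   tube giving maximum settling);
#' * impaction: branching-angle Stokes formula of the Yeh-Schum family,
#'   `p_imp = 1 - (2/pi) acos(theta St) + (1/pi) sin(2 acos(theta St))`
#'   for `theta St < 1`, else 1, with `St = rho_p d^2 u Cc / (18 mu d_t)`
#'   and `theta` the branching angle in radians.
#'
#' @param d_nm particle diameter (nm), vectorised.
#' @param length_cm airway length (cm).
#' @param diameter_cm airway diameter (cm).
#' @param flow_m3s volumetric flow through the single airway (m^3/s).
#' @param branching_angle_deg branching angle (degrees) used by impaction.
#' @param gravity_angle_deg angle of the tube axis from horizontal
#'   (degrees); 0 maximises sedimentation.
#' @param particle_density particle density (kg/m^3).
#' @return deposition probability in \[0, 1\], vectorised over `d_nm`.
#' @export
tube_deposition_probability <- function(d_nm, length_cm, diameter_cm, flow_m3s,
                                        branching_angle_deg = 35,
                                        gravity_angle_deg = 45,
                                        particle_density = 1000) {
  if (length_cm <= 0 || diameter_cm <= 0 || flow_m3s <= 0) {
    abort("airway geometry and flow must be positive")
  }
  L <- length_cm / 100
  dt <- diameter_cm / 100
  u <- flow_m3s / (pi * (dt / 2)^2)

  # diffusion
  D <- particle_diffusivity(d_nm)
  delta <- pi * D * L / (4 * flow_m3s)
  p_diff <- .ingham_diffusion(delta)

  # sedimentation (Yeh-Schum inclined tube)
  vs <- settling_velocity(d_nm, particle_density)
  eps <- 3 * vs * L * cos(gravity_angle_deg * pi / 180) / (4 * u * dt)
  eps <- pmin(eps, 1)
  p_sed <- 1 - exp(-4 * eps / pi)

  # impaction
  stk <- particle_density * (d_nm * 1e-9)^2 * u * cunningham_slip(d_nm) /
    (18 * .AIR$viscosity * dt)
  x <- pmin(branching_angle_deg * pi / 180 * stk, 1)
  a <- acos(x)
  p_imp <- pmin(pmax(1 - 2 / pi * a + sin(2 * a) / pi, 0), 1)

  pmin(1 - (1 - p_diff) * (1 - p_sed) * (1 - p_imp), 1)
}

#' Extrathoracic (nasal) deposition efficiency
#'
#' Single-pass nasal filtration efficiency, combining a Cheng-style
#' diffusional term `eta_diff = 1 - exp(-a * D^0.5 * Q^-0.28)` (D in cm^2/s,
#' Q in L/min) with an impaction-parameter sigmoid of the Yu family,
#' `eta_imp = ip / (ip + c_imp)` with `ip = d_um^2 * Q` (um^2 L/min), as
#' `1 - (1 - eta_diff)(1 - eta_imp)`.
#'
#' The default diffusional coefficient is a shipped calibration: `a` is set
#' so that the inspiratory efficiency of the 1 nm unattached cluster at
#' 18 L/min equals 0.90, the anchor the whole-lung cascade is built around.
#' All coefficients are arguments, so published coefficient sets can be
#' substituted directly.
#'
#' @param d_nm particle diameter (nm), vectorised.
#' @param flow_Lmin inspiratory (or expiratory) flow (L/min).
#' @param a_diff diffusional coefficient; default calibrated (see above).
#' @param c_imp impaction-parameter half-saturation constant (um^2 L/min).
#' @return efficiency in \[0, 1\].
#' @export
#' @examples
#' extrathoracic_efficiency(1, 18) # ~0.90 by calibration
extrathoracic_efficiency <- function(d_nm, flow_Lmin,
                                     a_diff = calibrated_defaults()$et_a_diff,
                                     c_imp = 3000) {
  if (any(d_nm <= 0) || flow_Lmin <= 0) abort("diameter and flow must be positive")
  D_cm2s <- particle_diffusivity(d_nm) * 1e4
  eta_d <- 1 - exp(-a_diff * sqrt(D_cm2s) * flow_Lmin^-0.28)
  ip <- (d_nm * 1e-3)^2 * flow_Lmin
  eta_i <- ip / (ip + c_imp)
  pmin(pmax(1 - (1 - eta_d) * (1 - eta_i), 0), 1)
}
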