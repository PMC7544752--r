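# Generation-averaged symmetric airway tree used by the typical-path
# whole-lung cascade and the mucociliary escalator.

#' Generation-averaged airway morphometry table
#'
#' Symmetric dichotomous tree, trachea = generation 1, with `2^(g-1)` airways
#' in generation `g`. Bronchial lengths for generations 6-16 and the mucus
#' velocities for generations 6-16 follow the packaged escalator table (9.0
#' mm / 0.74 mm/min at generation 6 down to 1.65 mm / 0.01 mm/min at
#' generation 16); generations 4-5 match the target-bifurcation geometry
#' (parent 0.72 cm x 0.56 cm, daughter 1.20 cm x 0.45 cm); the remaining
#' generations use Weibel-style symmetric-tree defaults. Tracheal mucus
#' velocity is 5.5 mm/min, decreasing monotonically to 0.01 mm/min at
#' generation 16; acinar generations (>= 17) carry no mucociliary clearance
#' and have `NA` velocity.
#'
#' @param jitter_gsd optional geometric standard deviation for a lognormal
#'   multiplicative jitter applied to lengths and diameters (stochastic
#'   geometry sensitivity runs); `NULL` = deterministic table.
#' @return tibble with columns `generation`, `length_cm`, `diameter_cm`,
#'   `branching_angle_deg`, `gravity_angle_deg`, `airway_count`,
#'   `mucus_velocity_mm_min`.
#' @export
airway_morphometry <- function(jitter_gsd = NULL) {
  length_cm <- c(
    12.0, 4.76, 1.90, 0.72, 1.20,
    0.90, 0.76, 0.64, 0.54, 0.46, 0.39, 0.33, 0.27, 0.23, 0.20, 0.165,
    0.141, 0.117, 0.099, 0.083, 0.070, 0.059, 0.050, 0.042, 0.036, 0.031
  )
  diameter_cm <- c(
    1.80, 1.22, 0.83, 0.56, 0.45,
    0.35, 0.28, 0.23, 0.186, 0.154, 0.130, 0.109, 0.095, 0.082, 0.074, 0.066,
    0.060, 0.054, 0.050, 0.047, 0.045, 0.043, 0.041, 0.041, 0.041, 0.041
  )
  mucus_velocity <- c(
    5.5, 3.8, 2.6, 1.6, 1.0,
    0.74, 0.50, 0.33, 0.22, 0.15, 0.10, 0.07, 0.05, 0.03, 0.02, 0.01,
    rep(NA_real_, 10)
  )
  tb <- tibble(
    generation = 1:26,
    length_cm = length_cm,
    diameter_cm = diameter_cm,
    branching_angle_deg = 35,
    gravity_angle_deg = 45,
    airway_count = 2^(0:25),
    mucus_velocity_mm_min = mucus_velocity
  )
  if (!is.null(jitter_gsd)) {
    stopifnot(jitter_gsd >= 1)
    n <- nrow(tb)
    tb$length_cm <- tb$length_cm * exp(rnorm(n, 0, log(jitter_gsd)))
    tb$diameter_cm <- tb$diameter_cm * exp(rnorm(n, 0, log(jitter_gsd)))
  }
  tb
}

#' Tidal penetration depth of the inhaled air front
#'
#' Deepest generation whose cumulative tree volume (from the trachea) fits
#' inside one tidal volume; the typical-path cascade marches particles to
#' this generation and reverses there on exhalation.
#'
#' @param morphometry morphometry table, see [airway_morphometry()].
#' @param tidal_L tidal volume (L).
#' @return generation number (integer).
#' @export
tidal_reach_generation <- function(morphometry = airway_morphometry(),
                                   tidal_L = 0.75) {
  vol_cm3 <- with(
    morphometry,
    airway_count * pi * (diameter_cm / 2)^2 * length_cm
  )
  cum <- cumsum(vol_cm3)
  g <- max(which(cum <= tidal_L * 1000))
  max(g, 1L)
}
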