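#' Shipped calibration constants
#'
#' Central registry of the package's calibrated surrogate parameters. These
#' are the quantities the source measurements do not pin down numerically
#' (the per-nuclide unattached shares of the indoor activity size
#' distribution, the attached-mode parameters, the nasal diffusional
#' coefficient, the alveolar mixing retention, the carinal slow-zone shape
#' and the deposition hot-spot mixture). Each was fitted once against the
#' anchor quantities of the modelled exposure -- 90% inspiratory nasal
#' efficiency of the 1 nm cluster, ~8% / ~5.7% bifurcation entry during
#' inhalation / exhalation, 20 +/- 1.7 min (max ~29 min) mucus residence
#' statistics and a deposition-only maximum patch enhancement factor of
#' ~423 -- and then frozen. They are calibrated values, not measured ones.
#'
#' @return named list of calibration constants:
#' \describe{
#'   \item{et_a_diff}{nasal diffusional coefficient `a` of
#'     [extrathoracic_efficiency()].}
#'   \item{unattached_fraction}{named list, per-nuclide unattached activity
#'     share.}
#'   \item{attached_gm_nm, attached_gsd}{attached-mode lognormal parameters.}
#'   \item{alveolar_mixing}{fraction of particles carried past the tidal
#'     front that stays behind in residual air instead of being exhaled.}
#'   \item{slow_zone_depth}{fractional mucus-speed reduction at the carinal
#'     ridge apex (0 = no zone, 1 = full stop).}
#'   \item{slow_zone_sigma_mm}{extent (mm) of the slow zone.}
#'   \item{slow_zone_shape}{exponent of the generalised-Gaussian zone
#'     profile (2 = Gaussian).}
#'   \item{hotspot_weight_inhalation}{weight of the concentrated carinal
#'     component of the inhalation deposition-site mixture.}
#'   \item{hotspot_weight_exhalation}{same for exhalation (close to
#'     uniform).}
#'   \item{hotspot_sigma_mm}{kernel bandwidth (mm) of the carinal
#'     component.}
#' }
#' @export
calibrated_defaults <- function() {
  list(
    et_a_diff = 21.94,
    unattached_fraction = list(po218 = 0.52, pb214 = 0.31, bi214 = 0.186),
    attached_gm_nm = 275,
    attached_gsd = 2.0,
    alveolar_mixing = 0.10,
    slow_zone_depth = 0.9985,
    slow_zone_sigma_mm = 2.55,
    slow_zone_shape = 0.90,
    hotspot_weight_inhalation = 0.8,
    hotspot_weight_exhalation = 0.05,
    hotspot_sigma_mm = 0.2515
  )
}
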