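# Activity-weighted particle size distributions of the three progenies and
# their transformation to number distributions.

#' Bimodal activity-weighted size distribution of a radon progeny
#'
#' Two-mode lognormal mixture on a geometric diameter grid: an unattached
#' (molecular-cluster) mode around 1 nm and an attached (ambient-aerosol)
#' mode in the accumulation range. The per-nuclide unattached activity
#' shares and the attached-mode parameters are shipped calibration values
#' (see [calibrated_defaults()]); measured indoor distributions are not
#' machine-readable, so the mixture is tuned once against the whole-lung
#' anchor quantities and then frozen.
#'
#' @param nuclide one of `"po218"`, `"pb214"`, `"bi214"`.
#' @param unattached_fraction activity share of the unattached mode.
#' @param unattached_gm_nm,unattached_gsd geometric mean (nm) / geometric sd
#'   of the unattached mode.
#' @param attached_gm_nm,attached_gsd geometric mean (nm) / geometric sd of
#'   the attached mode.
#' @param n_bins number of diameter bins.
#' @param d_range_nm diameter grid range (nm).
#' @return tibble with columns `nuclide`, `d_nm` (bin geometric midpoint)
#'   and `activity_fraction` (sums to 1).
#' @export
activity_size_distribution <- function(nuclide,
                                       unattached_fraction = calibrated_defaults()$unattached_fraction[[nuclide]],
                                       unattached_gm_nm = 1.0,
                                       unattached_gsd = 1.3,
                                       attached_gm_nm = calibrated_defaults()$attached_gm_nm,
                                       attached_gsd = calibrated_defaults()$attached_gsd,
                                       n_bins = 32,
                                       d_range_nm = c(0.5, 2000)) {
  stopifnot(unattached_fraction >= 0, unattached_fraction <= 1)
  edges <- exp(seq(log(d_range_nm[1]), log(d_range_nm[2]), length.out = n_bins + 1))
  mid <- sqrt(edges[-1] * edges[-(n_bins + 1)])
  mass <- function(gm, gsd) {
    p <- diff(plnorm(edges, meanlog = log(gm), sdlog = log(gsd)))
    p / sum(p)
  }
  frac <- unattached_fraction * mass(unattached_gm_nm, unattached_gsd) +
    (1 - unattached_fraction) * mass(attached_gm_nm, attached_gsd)
  tibble(nuclide = nuclide, d_nm = mid, activity_fraction = frac / sum(frac))
}

#' Transform an activity distribution to a number distribution
#'
#' Within one nuclide every airborne particle carries a single atom of that
#' nuclide, so per-bin number concentration is per-bin activity
#' concentration divided by the decay constant. When a total number
#' concentration is supplied (the configured ambient values), the number
#' distribution is rescaled to it; the shape is unchanged either way.
#'
#' @param dist activity size distribution tibble (see
#'   [activity_size_distribution()]) with an optional column
#'   `activity_Bq_m3` of per-bin activity concentration; if absent,
#'   `activity_fraction * total_activity_Bq_m3` is used.
#' @param decay_constant decay constant of the nuclide (1/s), `> 0`.
#' @param total_activity_Bq_m3 total airborne activity concentration.
#' @param total_number_m3 optional configured total number concentration to
#'   rescale to (pass-through of the ambient measurement).
#' @return the tibble with an added `number_m3` column.
#' @export
#' @examples
#' d <- tibble::tibble(nuclide = "po218", d_nm = 1, activity_fraction = 1)
#' activity_to_number(d, 3.788e-3, total_activity_Bq_m3 = 26.68)
activity_to_number <- function(dist, decay_constant,
                               total_activity_Bq_m3 = 1,
                               total_number_m3 = NULL) {
  if (decay_constant <= 0) abort("`decay_constant` must be positive")
  act <- dist[["activity_Bq_m3"]] %||%
    (dist$activity_fraction * total_activity_Bq_m3)
  num <- act / decay_constant
  if (!is.null(total_number_m3)) {
    num <- num / sum(num) * total_number_m3
  }
  dist$number_m3 <- num
  dist
}
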