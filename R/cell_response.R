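# Closed-form cell-death and cell-transformation responses of bronchial
# epithelial cells to accumulated alpha dose, and the three-scenario
# comparison of hot-spot versus average damage.

#' Dose-response parameters
#'
#' Exponential high-LET survival parameter `gamma` (1.3 per Gy, rat
#' tracheal epithelial cells) and linear transformation coefficient
#' `alpha_t` (5e-4 per Gy, C3H10T1/2 fibroblasts).
#'
#' @param gamma 1/Gy, `> 0`.
#' @param alpha_t 1/Gy, `> 0`.
#' @return list of class `response_parameters`.
#' @export
response_parameters <- function(gamma = 1.3, alpha_t = 5e-4) {
  stopifnot(gamma > 0, alpha_t > 0)
  structure(list(gamma = gamma, alpha_t = alpha_t),
    class = "response_parameters"
  )
}

.check_dose <- function(D) {
  if (any(D < 0)) abort("dose must be non-negative")
}

#' Cell survival probability
#'
#' `S(D) = exp(-gamma D)`, the single-hit exponential survival observed
#' for high-LET irradiation.
#'
#' @param D absorbed nucleus dose (Gy), vectorised.
#' @param params `response_parameters`.
#' @return probability in (0, 1].
#' @export
#' @examples
#' cell_survival(1)
cell_survival <- function(D, params = response_parameters()) {
  .check_dose(D)
  exp(-params$gamma * D)
}

#' Cell death probability
#'
#' `I(D) = 1 - S(D) = 1 - exp(-gamma D)`.
#'
#' @inheritParams cell_survival
#' @return probability in \[0, 1).
#' @export
cell_death_probability <- function(D, params = response_parameters()) {
  .check_dose(D)
  -expm1(-params$gamma * D)
}

#' Cell transformation probability
#'
#' `T(D) = alpha_t * D * exp(-gamma D)`: linear induction conditioned on
#' survival. Maximised at `D = 1/gamma` with value `alpha_t/(gamma e)`.
#'
#' @inheritParams cell_survival
#' @return probability, bounded by `alpha_t / (gamma * exp(1))`.
#' @export
cell_transformation_probability <- function(D, params = response_parameters()) {
  .check_dose(D)
  params$alpha_t * D * exp(-params$gamma * D)
}

#' Scenario comparison of cell death and transformation
#'
#' Per scenario, mean (and maximum) death and transformation probabilities
#' over the hot-spot nuclei and over the whole-wall average population,
#' with the standard ratios: hot-spot over scenario-average and
#' no-clearance over with-clearance. Dose accumulation is cumulative over
#' the exposure window before applying the dose responses.
#'
#' @param doses named list of tibbles (one per scenario, names e.g.
#'   `"uniform"`, `"no_clearance"`, `"with_clearance"`), each with columns
#'   `region` (`"hotspot"`/`"average"`), `dose_Gy`.
#' @param params `response_parameters`.
#' @return list with `summary` (scenario x region means/maxima) and
#'   `ratios` (`hotspot_over_average` per scenario and pairwise
#'   between-scenario hot-spot ratios).
#' @export
scenario_summary <- function(doses, params = response_parameters()) {
  if (length(names(doses)) != length(doses) || is.null(names(doses))) {
    abort("`doses` must be a named list of per-scenario dose tables")
  }
  summary <- purrr::imap_dfr(doses, function(tb, nm) {
    tb |>
      group_by(.data$region) |>
      summarise(
        n_nuclei = dplyr::n(),
        mean_dose_Gy = mean(.data$dose_Gy),
        mean_death = mean(cell_death_probability(.data$dose_Gy, params)),
        mean_transformation = mean(
          cell_transformation_probability(.data$dose_Gy, params)
        ),
        max_death = max(cell_death_probability(.data$dose_Gy, params)),
        max_transformation = max(
          cell_transformation_probability(.data$dose_Gy, params)
        ),
        .groups = "drop"
      ) |>
      mutate(scenario = nm, .before = 1)
  })
  hs <- summary |> filter(.data$region == "hotspot")
  av <- summary |> filter(.data$region == "average")
  hs_over_av <- left_join(hs, av, by = "scenario", suffix = c("_hs", "_av")) |>
    mutate(
      death_ratio = .data$mean_death_hs / .data$mean_death_av,
      transformation_ratio =
        .data$mean_transformation_hs / .data$mean_transformation_av
    ) |>
    select("scenario", "death_ratio", "transformation_ratio")
  pair <- NULL
  if (all(c("no_clearance", "with_clearance") %in% summary$scenario)) {
    a <- hs |> filter(.data$scenario == "no_clearance")
    b <- hs |> filter(.data$scenario == "with_clearance")
    pair <- tibble(
      comparison = "no_clearance / with_clearance (hotspot)",
      death_ratio = a$mean_death / b$mean_death,
      transformation_ratio = a$mean_transformation / b$mean_transformation
    )
  }
  list(summary = summary, ratios = list(
    hotspot_over_average = hs_over_av, clearance_effect = pair
  ))
}

#' Hot-spot and average nucleus doses for one simulated scenario
#'
#' Builds the two dose populations the scenario comparison needs from a
#' dynamic-simulation result: (i) the hot-spot tile centred on the carinal
#' apex, dosed by the alpha events that fall inside it (plus far-wall
#' arrivals at the surface-average rate); (ii) an average tile dosed by a
#' synthetic uniform event set at the scenario's surface-average alpha
#' density (the spatial mean dose; inhomogeneity hardly moves the mean).
#'
#' @param sim `bifsim_result`.
#' @param epithelium `epithelium_model`.
#' @param nuclei_hotspot,nuclei_average pre-sampled nucleus populations
#'   (tiles of `tile_mm`); sampled here when `NULL`.
#' @param tile_mm analysis tile edge (mm).
#' @param hotspot_radius_mm hot-spot radius around the apex used to select
#'   nuclei (and events) near the ridge.
#' @param geometry bifurcation geometry.
#' @param table stopping-power table.
#' @param n_tracks_per_event track multiplicity.
#' @param n_average_events sampled event count for the average tile (their
#'   weights compensate so the expected areal density is unchanged).
#' @return tibble with `region`, `type`, `dose_Gy`, `hits` per nucleus.
#' @export
scenario_doses <- function(sim, epithelium = epithelium_model(),
                           nuclei_hotspot = NULL, nuclei_average = NULL,
                           tile_mm = 1, hotspot_radius_mm = 0.5,
                           geometry = bifurcation_geometry(),
                           table = stopping_power_table(),
                           n_tracks_per_event = 10,
                           n_average_events = 1000) {
  alpha <- sim$events |> filter(!is.na(.data$alpha_energy_MeV))
  total_area <- sum(surface_areas_mm2(geometry)["total"])
  avg_rate <- sum(alpha$weight) / total_area # alpha / mm^2 (weighted)

  nuclei_hotspot <- nuclei_hotspot %||% sample_nuclei(epithelium, tile_mm)
  nuclei_average <- nuclei_average %||% sample_nuclei(epithelium, tile_mm)

  # --- hot-spot tile: events inside the tile, in apex-chart coordinates
  cc <- carina_chart_coords(
    alpha$branch, alpha$axial_mm, alpha$azimuth_deg, geometry
  )
  sel <- abs(cc$u_mm) <= tile_mm / 2 & abs(cc$w_mm) <= tile_mm / 2
  ev_hot <- tibble(
    x_mm = cc$u_mm[sel], y_mm = cc$w_mm[sel],
    energy_MeV = alpha$alpha_energy_MeV[sel], weight = alpha$weight[sel]
  )
  dose_hot <- nucleus_doses(
    ev_hot, nuclei_hotspot, epithelium, table,
    n_tracks_per_event = n_tracks_per_event, tile_mm = tile_mm,
    background_rate_per_mm2 = avg_rate,
    background_energy_MeV = alpha$alpha_energy_MeV,
    lumen_diameter_cm = geometry$daughter_diameter_cm
  ) |>
    filter(sqrt(.data$x_um^2 + .data$y_um^2) <= hotspot_radius_mm * 1000) |>
    mutate(region = "hotspot")

  # --- average tile: uniform events at the surface-average density,
  # oversampled with compensating weights so the tiny expected count does
  # not leave the tile dose at zero
  n_avg <- n_average_events
  w_avg <- avg_rate * tile_mm^2 / max(n_avg, 1)
  ev_avg <- tibble(
    x_mm = runif(n_avg, -tile_mm / 2, tile_mm / 2),
    y_mm = runif(n_avg, -tile_mm / 2, tile_mm / 2),
    energy_MeV = sample(alpha$alpha_energy_MeV, n_avg, replace = TRUE),
    weight = rep(w_avg, n_avg)
  )
  dose_avg <- nucleus_doses(
    ev_avg, nuclei_average, epithelium, table,
    n_tracks_per_event = n_tracks_per_event, tile_mm = tile_mm,
    background_rate_per_mm2 = avg_rate,
    background_energy_MeV = alpha$alpha_energy_MeV,
    lumen_diameter_cm = geometry$daughter_diameter_cm
  ) |>
    mutate(region = "average")

  bind_rows(dose_hot, dose_avg) |>
    select("region", "nucleus_id", "type", "depth_um", "dose_Gy", "hits")
}
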