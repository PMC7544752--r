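# Generation-wise mucociliary escalator: transit times from the deposition
# generation up to the generation-5 inlets, and the surviving/in-grown
# nuclide composition on arrival.

#' Escalator table for generations 6-16
#'
#' Average airway lengths and mucus velocities of the bronchial generations
#' that drain through the target bifurcation, with the cumulative clearance
#' time to the generation-5 inlet. A particle deposited in generation `g`
#' is taken to ride the mucus over the full length of every generation
#' `6..g` (including its own), so the cumulative time is
#' `sum(length/velocity)`; times are kept unrounded internally and rounded
#' to whole seconds only in the `clearance_time_s` report column.
#'
#' @param morphometry airway tree, see [airway_morphometry()].
#' @param half_length_start if `TRUE`, the deposition generation
#'   contributes only half its length (deposition-position averaging);
#'   default `FALSE`.
#' @return tibble with `generation` (6-16), `length_mm`,
#'   `velocity_mm_min`, `clearance_time_s` (rounded) and
#'   `clearance_time_exact_s`.
#' @export
escalator_table <- function(morphometry = airway_morphometry(),
                            half_length_start = FALSE) {
  rows <- filter(morphometry, .data$generation >= 6, .data$generation <= 16)
  if (any(is.na(rows$mucus_velocity_mm_min))) {
    abort("escalator generations must carry mucus velocities")
  }
  transit_s <- rows$length_cm * 10 / rows$mucus_velocity_mm_min * 60
  cum <- cumsum(transit_s)
  if (half_length_start) cum <- cum - transit_s / 2
  tibble(
    generation = rows$generation,
    length_mm = rows$length_cm * 10,
    velocity_mm_min = rows$mucus_velocity_mm_min,
    clearance_time_s = round(cum),
    clearance_time_exact_s = cum
  )
}

#' Cumulative clearance time from a generation to the generation-5 inlet
#'
#' @param gen deposition generation, 5-16 (5 is the degenerate empty path).
#' @param table escalator table, see [escalator_table()].
#' @param exact return the unrounded time.
#' @return time (s).
#' @export
#' @examples
#' cumulative_clearance_time(6) # 730 s
cumulative_clearance_time <- function(gen, table = escalator_table(),
                                      exact = FALSE) {
  if (any(gen < 5 | gen > max(table$generation))) {
    abort("`gen` must be within the escalator range (5-16)")
  }
  col <- if (exact) table$clearance_time_exact_s else table$clearance_time_s
  out <- numeric(length(gen))
  idx <- match(gen, table$generation)
  out[!is.na(idx)] <- col[idx[!is.na(idx)]]
  out # gen 5 rows keep 0
}

#' Up-cleared nuclide fractions from a deposition generation
#'
#' Evolves the deposited chain state over the cumulative clearance time of
#' the generation and reports, per nuclide, the arriving count relative to
#' that nuclide's own deposited count. In-growth can push the Bi-214
#' fraction above 100% when roughly twice as many Pb-214 as Bi-214 nuclei
#' are deposited and the transit is short. Fractions below the neglect
#' threshold (0.01%) are zeroed per (nuclide, source generation) pair.
#'
#' @param gen deposition generation (5-16).
#' @param deposited numeric length-3 deposited counts `(N1, N2, N3)`.
#' @param table escalator table.
#' @param nuclides nuclide table.
#' @param neglect_below fraction threshold (default `1e-4` = 0.01%).
#' @param exact evolve over the unrounded transit time instead of the
#'   reported whole-second clearance time. The default `FALSE` matches the
#'   convention of the reported table, whose quoted percentages are
#'   evaluated at the rounded times.
#' @return tibble `nuclide`, `deposited`, `arrived`, `fraction` (arrived /
#'   deposited of the same nuclide; `NA` where nothing was deposited).
#' @export
#' @examples
#' upcleared_fractions(6, c(1000, 0, 0)) # Po-218 survival 6.29%
upcleared_fractions <- function(gen, deposited, table = escalator_table(),
                                nuclides = radon_nuclides(),
                                neglect_below = 1e-4, exact = FALSE) {
  stopifnot(length(deposited) == 3, length(gen) == 1)
  t_cl <- cumulative_clearance_time(gen, table, exact = exact)
  arrived <- bateman_evolve(deposited, t_cl,
    lambda = nuclides$decay_constant[1:3]
  )
  frac <- ifelse(deposited > 0, arrived / deposited, NA_real_)
  cut <- !is.na(frac) & frac < neglect_below
  frac[cut] <- 0
  arrived[cut] <- 0
  tibble(
    nuclide = nuclides$name[1:3],
    deposited = deposited, arrived = as.numeric(arrived), fraction = frac
  )
}

#' Steady-state nuclide flux entering the generation-5 daughter inlets
#'
#' Combines the whole-lung deposition rates in generations 6-16 with the
#' escalator's Bateman transfer to yield the nuclei/s of each species
#' arriving at the daughter-branch inlets of one target bifurcation. The
#' subtree accounting is explicit: of the `2^(g-1)` airways of generation
#' `g`, `2^(g-5)` drain through each generation-5 branch, i.e. a fraction
#' `2/16 = 1/8` of the whole-lung deposition rate drains through the
#' target's two daughters. Per (species, source-generation) contributions
#' below the neglect threshold of the source's own deposit are zeroed.
#' Contributions from generation `g` switch on at `t = clearance_time(g)`
#' after the start of exposure (`ramp_times_s`), supporting the
#' empty-airways start.
#'
#' @param wl `wholelung_result` providing the per-generation deposition
#'   fractions and the exposure (for absolute number rates).
#' @param table escalator table.
#' @param nuclides nuclide table.
#' @param neglect_below threshold (fraction of the source nuclide's own
#'   deposit), default 0.01%.
#' @return list of class `entry_flux`: tibble `flux` (`nuclide`,
#'   `rate_per_s` at steady state, for the two daughter inlets combined),
#'   tibble `by_source` (`nuclide`, `source_generation`, `rate_per_s`,
#'   `ramp_time_s`).
#' @export
build_entry_flux <- function(wl, table = escalator_table(),
                             nuclides = radon_nuclides(),
                             neglect_below = 1e-4) {
  gens_needed <- table$generation
  dep <- wl$generations |>
    filter(.data$generation %in% gens_needed) |>
    group_by(.data$nuclide, .data$generation) |>
    summarise(fraction = sum(.data$fraction), .groups = "drop")
  if (!all(gens_needed %in% unique(dep$generation))) {
    abort("whole-lung result lacks deposition rows for escalator generations")
  }
  # absolute inhaled number rate per species (1/s, cycle-averaged)
  br <- wl$exposure$breathing
  minute_volume_m3s <- br$tidal_L * br$frequency_per_min / 1000 / 60
  conc <- wl$exposure$number_concentration_m3
  chain <- nuclides$name[1:3]
  inhaled_rate <- conc[chain] * minute_volume_m3s

  by_source <- purrr::map_dfr(gens_needed, function(g) {
    d <- dep |> filter(.data$generation == g)
    dvec <- setNames(d$fraction, d$nuclide)[chain] * inhaled_rate
    t_g <- cumulative_clearance_time(g, table, exact = TRUE)
    M <- bateman_matrix(t_g, nuclides$decay_constant[1:3])
    arrived <- as.numeric(M %*% dvec)
    frac_own <- ifelse(dvec > 0, arrived / dvec, 0)
    arrived[frac_own < neglect_below] <- 0
    tibble(
      nuclide = chain, source_generation = g,
      rate_per_s = arrived / 8, # subtree: 2 of 16 generation-5 branches
      ramp_time_s = t_g
    )
  })
  flux <- by_source |>
    group_by(.data$nuclide) |>
    summarise(rate_per_s = sum(.data$rate_per_s), .groups = "drop")
  structure(list(flux = flux, by_source = by_source), class = "entry_flux")
}
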