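# Deterministic typical-path whole-lung deposition cascade: extrathoracic
# filtration, generation-by-generation transit during inhalation, reversal
# at the tidal front, and the return pass during exhalation.

# nasal + pharyngeal dead-space volume ahead of the trachea (cm^3)
.ET_VOLUME_CM3 <- 50

#' Default radiation exposure and breathing scenario
#'
#' Indoor exposure: 46 Bq/m^3 equilibrium radon, progeny activity ratios
#' 0.58/0.44/0.29 (Po-218 : Pb-214 : Bi-214/Po-214, relative to radon),
#' equilibrium factor 0.4, ambient particle number concentrations
#' 7,820/51,270/25,090 m^-3. Breathing: nasal tidal breathing of a sitting
#' adult male, 18 L/min inspiratory flow, 12 min^-1, 0.75 L tidal volume,
#' 3.3 L functional residual capacity.
#'
#' @return nested list with elements `radon_Bq_m3`, `ratios`,
#'   `equilibrium_factor`, `number_concentration_m3`, `breathing` and the
#'   size-distribution calibration (`unattached_fraction`, `attached_gm_nm`,
#'   `attached_gsd`), ET coefficients and `alveolar_mixing`.
#' @export
default_exposure <- function() {
  cal <- calibrated_defaults()
  list(
    radon_Bq_m3 = 46,
    ratios = c(po218 = 0.58, pb214 = 0.44, bi214 = 0.29),
    equilibrium_factor = 0.4,
    number_concentration_m3 = c(po218 = 7820, pb214 = 51270, bi214 = 25090),
    breathing = list(
      mode = "nasal", flow_Lmin = 18, frequency_per_min = 12,
      tidal_L = 0.75, frc_L = 3.3
    ),
    unattached_fraction = cal$unattached_fraction,
    unattached_gm_nm = 1.0, unattached_gsd = 1.3,
    attached_gm_nm = cal$attached_gm_nm, attached_gsd = cal$attached_gsd,
    et = list(a_diff_in = cal$et_a_diff, a_diff_ex = cal$et_a_diff, c_imp = 3000),
    alveolar_mixing = cal$alveolar_mixing
  )
}

#' Airborne activity concentrations of the progenies
#'
#' @param exposure exposure list, see [default_exposure()].
#' @return named numeric (Bq/m^3) for po218, pb214, bi214.
#' @export
progeny_activity_Bq_m3 <- function(exposure = default_exposure()) {
  exposure$radon_Bq_m3 * exposure$ratios
}

#' Whole-lung deposition cascade
#'
#' Marches every size bin of every progeny through the extrathoracic region
#' and down the symmetric airway tree during inhalation, reverses the flow
#' at the tidal-front generation (a calibrated `alveolar_mixing` share of
#' the flux that reaches the front stays behind in residual air), and
#' marches the survivors back out during exhalation. Per-airway flows halve
#' at every bifurcation; flow split is symmetric; hygroscopic growth is not
#' applied (growth factor 1 for all sizes).
#'
#' All fractions are relative to the inhaled amount of the same nuclide
#' (for a single nuclide, number-weighted and activity-weighted fractions
#' coincide because every particle carries one atom).
#'
#' @param exposure exposure scenario, see [default_exposure()].
#' @param morphometry airway tree, see [airway_morphometry()].
#' @param target_generation generation of the target bifurcation's parent
#'   branch (4: a segmental bronchus whose daughters are generation 5).
#' @param n_bins size-grid resolution.
#' @return object of class `wholelung_result`: a list with tibbles
#'   `extrathoracic` (nuclide, phase, fraction), `generations` (nuclide,
#'   generation, phase, fraction), `inlet_flux` (per-bin fraction of the
#'   nuclide's inhaled number arriving at the target-generation inlet,
#'   columns nuclide, phase, d_nm, fraction -- whole-generation flux, i.e.
#'   before dividing among parallel airways), `retained` and `exhaled`
#'   per-nuclide fractions, plus `summary` (also returned by `tidy()`).
#' @export
simulate_whole_lung <- function(exposure = default_exposure(),
                                morphometry = airway_morphometry(),
                                target_generation = 4,
                                n_bins = 32) {
  mph <- arrange(morphometry, .data$generation)
  if (!identical(mph$generation, seq_len(nrow(mph)))) {
    abort("`morphometry` must cover generations 1..G without gaps")
  }
  br <- exposure$breathing
  reach <- tidal_reach_generation(mph, br$tidal_L)
  Q_m3s <- br$flow_Lmin / 1000 / 60
  nucl <- c("po218", "pb214", "bi214")
  act <- progeny_activity_Bq_m3(exposure)

  per_nuclide <- purrr::map(nucl, function(nu) {
    dist <- activity_size_distribution(
      nu,
      unattached_fraction = exposure$unattached_fraction[[nu]],
      unattached_gm_nm = exposure$unattached_gm_nm,
      unattached_gsd = exposure$unattached_gsd,
      attached_gm_nm = exposure$attached_gm_nm,
      attached_gsd = exposure$attached_gsd,
      n_bins = n_bins
    )
    d <- dist$d_nm
    f <- dist$activity_fraction
    p_gen <- vapply(seq_len(reach), function(g) {
      tube_deposition_probability(
        d,
        length_cm = mph$length_cm[g], diameter_cm = mph$diameter_cm[g],
        flow_m3s = Q_m3s / mph$airway_count[g],
        branching_angle_deg = mph$branching_angle_deg[g],
        gravity_angle_deg = mph$gravity_angle_deg[g]
      )
    }, numeric(length(d)))

    # -- plug-flow penetration: the share of tidal air (and of the airborne
    # particles it carries) that proceeds past generation g; late-inhaled
    # air turns around inside the bronchial tree (last in, first out)
    vol_cm3 <- with(mph, airway_count * pi * (diameter_cm / 2)^2 * length_cm)
    cumvol <- .ET_VOLUME_CM3 + cumsum(vol_cm3)
    reach_frac <- pmax(0, 1 - cumvol[seq_len(reach)] / (br$tidal_L * 1000))
    # air in the alveolated region mixes with residual air; a calibrated
    # share of the particles it carries stays behind
    alveolated <- seq_len(reach) > 16

    # -- inhalation
    eta_in <- extrathoracic_efficiency(d, br$flow_Lmin,
      a_diff = exposure$et$a_diff_in, c_imp = exposure$et$c_imp
    )
    et_in <- sum(f * eta_in)
    f <- f * (1 - eta_in)
    dep_in <- matrix(0, length(d), reach)
    halted <- matrix(0, length(d), reach) # inventory turning around in g
    flux_target_in <- NULL
    for (g in seq_len(reach)) {
      if (g == target_generation) flux_target_in <- f
      dep_in[, g] <- f * p_gen[, g]
      f <- f * (1 - p_gen[, g])
      keep <- if (g < reach) reach_frac[g + 1] / max(reach_frac[g], 1e-12) else 0
      halted[, g] <- f * (1 - keep)
      f <- f * keep
    }
    retained <- rowSums(halted[, alveolated, drop = FALSE]) *
      exposure$alveolar_mixing
    halted[, alveolated] <- halted[, alveolated] * (1 - exposure$alveolar_mixing)

    # -- exhalation (reverse transit, symmetric flow; parcels re-mobilise
    # in depth order)
    dep_ex <- matrix(0, length(d), reach)
    flux_target_ex <- NULL
    f <- numeric(length(d))
    for (g in rev(seq_len(reach))) {
      f <- f + halted[, g]
      if (g == target_generation + 1) flux_target_ex <- f
      dep_ex[, g] <- f * p_gen[, g]
      f <- f * (1 - p_gen[, g])
    }
    eta_ex <- extrathoracic_efficiency(d, br$flow_Lmin,
      a_diff = exposure$et$a_diff_ex, c_imp = exposure$et$c_imp
    )
    et_ex <- sum(f * eta_ex)
    exhaled <- f * (1 - eta_ex)

    list(
      nuclide = nu, d_nm = d,
      et = c(inhalation = et_in, exhalation = et_ex),
      dep_in = dep_in, dep_ex = dep_ex,
      flux_in = flux_target_in, flux_ex = flux_target_ex,
      retained = sum(retained), exhaled = sum(exhaled),
      activity_Bq_m3 = unname(act[nu])
    )
  })

  gens <- purrr::map_dfr(per_nuclide, function(x) {
    bind_rows(
      tibble(
        nuclide = x$nuclide, generation = seq_len(ncol(x$dep_in)),
        phase = "inhalation", fraction = colSums(x$dep_in)
      ),
      tibble(
        nuclide = x$nuclide, generation = seq_len(ncol(x$dep_ex)),
        phase = "exhalation", fraction = colSums(x$dep_ex)
      )
    )
  })
  et <- purrr::map_dfr(per_nuclide, function(x) {
    tibble(
      nuclide = x$nuclide, phase = c("inhalation", "exhalation"),
      fraction = unname(x$et)
    )
  })
  inlet <- purrr::map_dfr(per_nuclide, function(x) {
    bind_rows(
      tibble(
        nuclide = x$nuclide, phase = "inhalation", d_nm = x$d_nm,
        fraction = x$flux_in
      ),
      tibble(
        nuclide = x$nuclide, phase = "exhalation", d_nm = x$d_nm,
        fraction = x$flux_ex
      )
    )
  })
  bookkeeping <- purrr::map_dfr(per_nuclide, function(x) {
    tibble(
      nuclide = x$nuclide, retained = x$retained, exhaled = x$exhaled,
      activity_Bq_m3 = x$activity_Bq_m3
    )
  })

  out <- list(
    extrathoracic = et, generations = gens, inlet_flux = inlet,
    bookkeeping = bookkeeping,
    target_generation = target_generation, reach_generation = reach,
    exposure = exposure, morphometry = mph
  )
  class(out) <- "wholelung_result"
  out
}

#' Activity-weighted fraction of inhaled activity entering the target
#' bifurcation
#'
#' Inhalation entry is the surviving activity flux at the inlet of the
#' target generation divided among its parallel airways; exhalation entry
#' is the returning flux at the daughter-generation inlets divided among
#' the parallel daughter pairs (equivalently, the same subtree factor
#' `2^(target_generation - 1)`).
#'
#' @param wl `wholelung_result`.
#' @param phase `"inhalation"` or `"exhalation"`.
#' @return scalar fraction (of total inhaled activity of all progenies).
#' @export
bifurcation_entry_fraction <- function(wl, phase = c("inhalation", "exhalation")) {
  phase <- match.arg(phase)
  n_parallel <- 2^(wl$target_generation - 1)
  act <- setNames(wl$bookkeeping$activity_Bq_m3, wl$bookkeeping$nuclide)
  fx <- filter(wl$inlet_flux, .data$phase == !!phase)
  per_nu <- fx |>
    group_by(.data$nuclide) |>
    summarise(fraction = sum(.data$fraction), .groups = "drop")
  sum(per_nu$fraction * act[per_nu$nuclide]) / sum(act) / n_parallel
}

#' Deposition efficiency of the target bifurcation
#'
#' Activity-weighted efficiency of the two-generation bifurcation unit
#' (parent plus daughter tube in series), evaluated with the analytic
#' diffusion / sedimentation / impaction mechanisms on the size
#' distribution actually arriving at the unit in the given phase.
#'
#' @param wl `wholelung_result` (its `inlet_flux` supplies the entering
#'   distribution).
#' @param phase `"inhalation"` or `"exhalation"`.
#' @param geometry bifurcation geometry, see [bifurcation_geometry()].
#' @param flow_Lmin whole-lung flow (L/min) during the phase.
#' @return scalar efficiency in \[0, 1\].
#' @export
bifurcation_deposition_efficiency <- function(wl,
                                              phase = c("inhalation", "exhalation"),
                                              geometry = bifurcation_geometry(),
                                              flow_Lmin = wl$exposure$breathing$flow_Lmin) {
  phase <- match.arg(phase)
  fx <- filter(wl$inlet_flux, .data$phase == !!phase)
  if (nrow(fx) == 0 || sum(fx$fraction) <= 0) {
    abort("empty entering distribution")
  }
  act <- setNames(wl$bookkeeping$activity_Bq_m3, wl$bookkeeping$nuclide)
  w <- fx$fraction * act[fx$nuclide]
  p <- bifurcation_unit_probability(fx$d_nm, geometry, flow_Lmin,
    parent_generation = wl$target_generation
  )
  sum(w * p) / sum(w)
}

#' Deposition probability of one pass through the bifurcation unit
#'
#' Serial combination of the parent and daughter tube probabilities at the
#' unit's own per-airway flows.
#'
#' @param d_nm particle diameters (nm).
#' @param geometry bifurcation geometry.
#' @param flow_Lmin whole-lung flow (L/min).
#' @param parent_generation generation number of the parent branch.
#' @return vector of probabilities.
#' @export
bifurcation_unit_probability <- function(d_nm, geometry = bifurcation_geometry(),
                                         flow_Lmin = 18, parent_generation = 4) {
  Q <- flow_Lmin / 1000 / 60
  qp <- Q / 2^(parent_generation - 1)
  p_par <- tube_deposition_probability(
    d_nm, geometry$parent_length_cm, geometry$parent_diameter_cm, qp,
    branching_angle_deg = geometry$bifurcation_angle_deg
  )
  p_dau <- tube_deposition_probability(
    d_nm, geometry$daughter_length_cm, geometry$daughter_diameter_cm, qp / 2,
    branching_angle_deg = geometry$bifurcation_angle_deg
  )
  1 - (1 - p_par) * (1 - p_dau)
}

#' @export
tidy.wholelung_result <- function(x, ...) {
  x$generations |>
    bind_rows(mutate(x$extrathoracic, generation = 0L)) |>
    arrange(.data$nuclide, .data$phase, .data$generation)
}

#' @export
glance.wholelung_result <- function(x, ...) {
  de_in <- bifurcation_deposition_efficiency(x, "inhalation")
  de_ex <- bifurcation_deposition_efficiency(x, "exhalation")
  en_in <- bifurcation_entry_fraction(x, "inhalation")
  en_ex <- bifurcation_entry_fraction(x, "exhalation")
  tibble(
    entry_inhalation = en_in, entry_exhalation = en_ex,
    de_inhalation = de_in, de_exhalation = de_ex,
    combined_deposited = en_in * de_in + en_ex * de_ex,
    reach_generation = x$reach_generation
  )
}

#' @export
print.wholelung_result <- function(x, ...) {
  g <- glance(x)
  cat("<wholelung_result>\n")
  cat(sprintf(
    "  entry into target bifurcation: %.2f%% (inhalation), %.2f%% (exhalation)\n",
    100 * g$entry_inhalation, 100 * g$entry_exhalation
  ))
  cat(sprintf(
    "  bifurcation deposition efficiency: %.2f%% / %.2f%%\n",
    100 * g$de_inhalation, 100 * g$de_exhalation
  ))
  cat(sprintf(
    "  combined deposited fraction: %.3f%%\n",
    100 * g$combined_deposited
  ))
  invisible(x)
}
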