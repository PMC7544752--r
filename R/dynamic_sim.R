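# Time-resolved simulation of deposition, clearance, transmutation and
# alpha decay inside the target bifurcation.
#
# A fixed-step reference scheme tracks particles on a 0.1 s grid
# (`step_bifurcation_sim()`). The production engine
# (`run_bifurcation_sim()`) samples the identical stochastic process
# event-by-event: deposition/entry times from the phase-gated Poisson
# sources, per-nucleus exponential decay clocks, deterministic streamline
# motion between events. Event-driven sampling is exact for this process
# (all rates are piecewise constant and motion is deterministic), so the
# fixed-step variant serves as a cross-check rather than the engine.

#' Simulation configuration
#'
#' @param scenario 1 = uniform deposition without clearance, 2 =
#'   inhomogeneous deposition without clearance, 3 = inhomogeneous
#'   deposition with clearance (entries from deeper airways and streamline
#'   motion active only in scenario 3).
#' @param hours exposure duration (h).
#' @param replication statistical replication factor: the physical source
#'   rates are multiplied by this and every tracked particle carries weight
#'   `1/replication`; expectation-preserving variance reduction for the
#'   sparse physical event rates (well below one deposit per second).
#' @param timestep_s step of the fixed-step validator scheme (s).
#' @param seed optional seed applied at the start of a run.
#' @param breathing_cycle_s breathing cycle length (s); the first half is
#'   inhalation, the second exhalation (12 min^-1 tidal breathing).
#' @param ramp_entry if `TRUE`, the up-cleared entry flux from each source
#'   generation switches on only after that generation's clearance time
#'   (the escalator itself also starts empty); the default `FALSE` applies
#'   the steady-state entry flux from `t = 0`, i.e. "empty airways" refers
#'   to the target bifurcation while the deeper escalator is already in
#'   equilibrium with the chronic exposure.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(scenario = 3, hours = 16, replication = 10,
                       timestep_s = 0.1, seed = NULL,
                       breathing_cycle_s = 5, ramp_entry = FALSE) {
  stopifnot(scenario %in% 1:3, hours >= 0, replication >= 1, timestep_s > 0)
  structure(
    list(
      scenario = scenario, hours = hours, replication = replication,
      timestep_s = timestep_s, seed = seed,
      breathing_cycle_s = breathing_cycle_s, ramp_entry = ramp_entry
    ),
    class = "sim_config"
  )
}

#' Source terms of the bifurcation simulation
#'
#' Converts the whole-lung cascade and the escalator entry flux into the
#' absolute per-second source rates of the target bifurcation: local
#' deposition rates per species and phase (deposits per second of that
#' phase), and daughter-inlet entry rates per species with their
#' empty-airways ramp times.
#'
#' @param wl `wholelung_result`.
#' @param entry `entry_flux` from [build_entry_flux()]; `NULL` computes it.
#' @param geometry bifurcation geometry.
#' @return list of class `bif_sources`: `deposition` tibble (`nuclide`,
#'   `phase`, `rate_per_s`), `entry` tibble (`nuclide`,
#'   `source_generation`, `rate_per_s`, `ramp_time_s`).
#' @export
bifurcation_sources <- function(wl, entry = NULL,
                                geometry = bifurcation_geometry()) {
  entry <- entry %||% build_entry_flux(wl)
  conc <- wl$exposure$number_concentration_m3
  Q <- wl$exposure$breathing$flow_Lmin / 1000 / 60 # m^3/s while flowing
  n_parallel <- 2^(wl$target_generation - 1)
  dep <- wl$inlet_flux |>
    mutate(
      p = bifurcation_unit_probability(.data$d_nm, geometry,
        flow_Lmin = wl$exposure$breathing$flow_Lmin,
        parent_generation = wl$target_generation
      )
    ) |>
    group_by(.data$nuclide, .data$phase) |>
    summarise(
      rate_per_s = sum(.data$fraction * .data$p) / n_parallel,
      .groups = "drop"
    ) |>
    mutate(rate_per_s = .data$rate_per_s * conc[.data$nuclide] * Q)
  structure(
    list(deposition = dep, entry = entry$by_source),
    class = "bif_sources"
  )
}

# sample times uniformly over the union of phase half-cycles in [0, T)
.sample_phase_times <- function(n, total_s, cycle_s, phase) {
  offset <- if (phase == "inhalation") 0 else cycle_s / 2
  u <- runif(n, 0, total_s / 2)
  cycle_s * floor(u / (cycle_s / 2)) + (u %% (cycle_s / 2)) + offset
}

#' Run the event-driven bifurcation simulation
#'
#' Starts from empty airways, samples all deposition and entry events of
#' the exposure, assigns each particle its nearest pre-computed clearance
#' trajectory, draws the full decay-chain history of the nucleus it
#' carries, and logs every decay with its location at decay time. In
#' scenarios 1-2 positions are frozen and there are no entries from the
#' deeper airways (no clearance); in scenario 3 particles ride the mucus
#' and leave at the parent outlet.
#'
#' @param config `sim_config`.
#' @param sources `bif_sources`; required for scenarios 2-3 (scenario 1
#'   uses the same local deposition rates with a uniform pattern).
#' @param trajectories `trajectory_set` (needed for scenario 3).
#' @param pattern_inhalation,pattern_exhalation deposition patterns; the
#'   defaults are phase-calibrated ([deposition_pattern()]); scenario 1
#'   forces both to background-only.
#' @param geometry bifurcation geometry.
#' @param nuclides nuclide table.
#' @return list of class `bifsim_result`: `events` (decay log: `time_s`,
#'   `species`, `branch`, `axial_mm`, `azimuth_deg`, `alpha_energy_MeV`,
#'   `weight`, `origin`), `particles` (final census), `activity` (per-
#'   minute species counts and summed activity), `bookkeeping` (exact
#'   weighted-nucleus conservation counters), `quasi_steady_min`, `config`.
#' @export
run_bifurcation_sim <- function(config, sources,
                                trajectories = NULL,
                                pattern_inhalation = deposition_pattern("inhalation"),
                                pattern_exhalation = deposition_pattern("exhalation"),
                                geometry = bifurcation_geometry(),
                                nuclides = radon_nuclides()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  if (config$scenario == 3 && is.null(trajectories)) {
    abort("scenario 3 requires a trajectory set")
  }
  if (config$scenario == 1) {
    pattern_inhalation <- deposition_pattern("inhalation", hotspot_weight = 0)
    pattern_exhalation <- deposition_pattern("exhalation", hotspot_weight = 0)
  }
  T_s <- config$hours * 3600
  R <- config$replication
  w <- 1 / R
  chain <- nuclides$name[1:3]

  parts <- list()
  # --- local deposition sources (phase-gated Poisson)
  for (ph in c("inhalation", "exhalation")) {
    pat <- if (ph == "inhalation") pattern_inhalation else pattern_exhalation
    for (nu in chain) {
      r <- sources$deposition |>
        filter(.data$nuclide == nu, .data$phase == ph) |>
        pull(.data$rate_per_s)
      if (length(r) == 0 || r <= 0 || T_s <= 0) next
      n <- rpois(1, r * T_s / 2 * R)
      if (n == 0) next
      pos <- sample_deposition_site(n, pat, geometry)
      parts[[length(parts) + 1]] <- pos |>
        mutate(
          species = nu, origin = "deposited",
          t0_s = .sample_phase_times(n, T_s, config$breathing_cycle_s, ph)
        )
    }
  }
  # --- entries from the deeper airways (scenario 3 only, continuous, ramped)
  if (config$scenario == 3 && T_s > 0) {
    for (k in seq_len(nrow(sources$entry))) {
      row <- sources$entry[k, ]
      t_on <- if (isTRUE(config$ramp_entry)) row$ramp_time_s else 0
      dur <- max(0, T_s - t_on)
      if (row$rate_per_s <= 0 || dur <= 0) next
      n <- rpois(1, row$rate_per_s * dur * R)
      if (n == 0) next
      parts[[length(parts) + 1]] <- tibble(
        branch = sample(c("daughter_a", "daughter_b"), n, replace = TRUE),
        axial_mm = 0,
        azimuth_deg = runif(n, 0, 360),
        species = row$nuclide, origin = "entered",
        t0_s = runif(n, t_on, T_s)
      )
    }
  }
  particles <- bind_rows(parts)
  n_p <- nrow(particles)

  if (n_p > 0) {
    # --- clearance: trajectory assignment and exit clocks
    if (config$scenario == 3) {
      particles$trajectory <- nearest_trajectory(
        trajectories, particles$branch, particles$axial_mm,
        particles$azimuth_deg
      )
      rem_min <- trajectory_time_remaining(
        trajectories, particles$trajectory, particles$branch,
        particles$axial_mm
      )
      particles$t_exit_s <- particles$t0_s + rem_min * 60
    } else {
      particles$trajectory <- NA_integer_
      particles$t_exit_s <- Inf
    }
    particles$weight <- w

    # --- decay chains (relative clocks), then the event log
    hist3 <- matrix(NA_real_, n_p, 3)
    for (nu in chain) {
      sel <- particles$species == nu
      if (any(sel)) {
        hist3[sel, ] <- as.matrix(sample_chain_history(nu, sum(sel), nuclides))
      }
    }
    ev <- list()
    alpha_of <- setNames(nuclides$alpha_energy_MeV[1:3], chain)
    for (k in 1:3) {
      t_abs <- particles$t0_s + hist3[, k]
      live <- !is.na(t_abs) & t_abs < pmin(particles$t_exit_s, T_s)
      if (!any(live)) next
      idx <- which(live)
      if (config$scenario == 3) {
        pos <- trajectory_position_after(
          trajectories, particles$trajectory[idx], particles$branch[idx],
          particles$axial_mm[idx], hist3[idx, k] / 60
        )
      } else {
        pos <- particles[idx, c("branch", "axial_mm", "azimuth_deg")]
      }
      ev[[k]] <- tibble(
        time_s = t_abs[idx], species = chain[k],
        branch = pos$branch, axial_mm = pos$axial_mm,
        azimuth_deg = pos$azimuth_deg,
        alpha_energy_MeV = unname(alpha_of[chain[k]]),
        weight = w, origin = particles$origin[idx],
        particle = idx
      )
    }
    events <- bind_rows(ev) |> arrange(.data$time_s)
  } else {
    particles <- tibble(
      branch = character(), axial_mm = numeric(), azimuth_deg = numeric(),
      species = character(), origin = character(), t0_s = numeric(),
      trajectory = integer(), t_exit_s = numeric(), weight = numeric()
    )
    hist3 <- matrix(NA_real_, 0, 3)
    events <- tibble(
      time_s = numeric(), species = character(), branch = character(),
      axial_mm = numeric(), azimuth_deg = numeric(),
      alpha_energy_MeV = numeric(), weight = numeric(), origin = character(),
      particle = integer()
    )
  }

  # --- per-minute species presence and activity
  lam <- setNames(nuclides$decay_constant[1:3], chain)
  t_grid <- if (T_s >= 60) seq(60, T_s, by = 60) else numeric(0)
  counts <- matrix(0, length(t_grid), 3, dimnames = list(NULL, chain))
  if (n_p > 0 && length(t_grid) > 0) {
    for (k in 1:3) {
      has <- !is.na(hist3[, k]) # particle passes through species k
      rel_start <- if (k > 1) ifelse(is.na(hist3[, k - 1]), 0, hist3[, k - 1]) else 0
      a <- (particles$t0_s + rel_start)[has]
      b <- pmin(particles$t0_s + hist3[, k], particles$t_exit_s)[has]
      keep <- b > a
      if (any(keep)) {
        counts[, k] <- .count_open_intervals(a[keep], b[keep], t_grid) * w
      }
    }
  }
  activity <- tibble(
    time_min = t_grid / 60,
    po218 = counts[, "po218"], pb214 = counts[, "pb214"],
    bi214 = counts[, "bi214"],
    activity_Bq = counts %*% lam[chain] |> as.numeric()
  )

  # --- exact weighted bookkeeping (nuclei by particle)
  is_out <- if (n_p > 0) particles$t_exit_s < T_s else logical(0)
  bookkeeping <- tibble(
    deposited = sum(particles$origin == "deposited") * w,
    entered = sum(particles$origin == "entered") * w,
    exited = sum(is_out) * w,
    in_residence = sum(!is_out) * w,
    alpha_decays = sum(events$weight[!is.na(events$alpha_energy_MeV)]),
    beta_decays = sum(events$weight[is.na(events$alpha_energy_MeV)])
  )

  out <- list(
    events = events, particles = particles, activity = activity,
    bookkeeping = bookkeeping, config = config,
    quasi_steady_min = .quasi_steady_minute(activity)
  )
  class(out) <- "bifsim_result"
  out
}

# number of intervals (a, b] covering each grid time
.count_open_intervals <- function(a, b, grid) {
  ga <- findInterval(grid, sort(a))
  gb <- findInterval(grid, sort(b))
  ga - gb
}

# first minute at which the centred 5-min moving mean of total activity is
# within 5% of the final 2-h mean (NA when never, or run too short)
.quasi_steady_minute <- function(activity, window_min = 5, tail_h = 2,
                                 tol = 0.05) {
  x <- activity$activity_Bq
  t <- activity$time_min
  if (length(x) < window_min || max(t) <= tail_h * 60) {
    return(NA_real_)
  }
  ref <- mean(x[t > max(t) - tail_h * 60])
  if (ref <= 0) {
    return(NA_real_)
  }
  run <- stats::filter(x, rep(1 / window_min, window_min), sides = 2)
  ok <- which(!is.na(run) & abs(run - ref) / ref <= tol)
  if (length(ok) == 0) NA_real_ else t[min(ok)]
}

#' @export
print.bifsim_result <- function(x, ...) {
  cat("<bifsim_result>\n")
  cat(sprintf(
    "  scenario %d, %.1f h, replication %d\n",
    x$config$scenario, x$config$hours, x$config$replication
  ))
  cat(sprintf(
    "  particles: %.1f deposited + %.1f entered (weighted)\n",
    x$bookkeeping$deposited, x$bookkeeping$entered
  ))
  cat(sprintf(
    "  decays: %.1f alpha, %.1f beta; quasi-steady at %s min\n",
    x$bookkeeping$alpha_decays, x$bookkeeping$beta_decays,
    format(x$quasi_steady_min)
  ))
  invisible(x)
}

#' @export
tidy.bifsim_result <- function(x, ...) {
  tidyr::pivot_longer(x$activity, -"time_min",
    names_to = "series", values_to = "value"
  )
}

#' @export
glance.bifsim_result <- function(x, ...) {
  dplyr::bind_cols(
    x$bookkeeping,
    tibble(
      quasi_steady_min = x$quasi_steady_min,
      mean_activity_Bq = mean(x$activity$activity_Bq)
    )
  )
}

#' Advance a fixed-step simulation state by one time step
#'
#' Reference 0.1 s-resolution scheme: per step it (1) draws new local
#' depositions from the phase-gated Poisson sources, (2) draws new
#' daughter-inlet entries, (3) advances particles along their assigned
#' trajectories, (4) applies the Bernoulli decay draw
#' `p = 1 - exp(-lambda dt)` to every tracked nucleus, records alpha
#' events and transmutes, and (5) removes particles passing the parent
#' outlet and nuclei reaching the terminal species. Used to cross-validate
#' the event-driven engine on short runs.
#'
#' @param state list as returned by [new_step_state()] or a previous call.
#' @param config `sim_config`.
#' @param sources `bif_sources`.
#' @param trajectories `trajectory_set` (scenario 3).
#' @param pattern_inhalation,pattern_exhalation deposition patterns.
#' @param geometry bifurcation geometry.
#' @param nuclides nuclide table.
#' @return updated state (fields `time_s`, `particles`, `events`,
#'   `counters`).
#' @export
step_bifurcation_sim <- function(state, config, sources,
                                 trajectories = NULL,
                                 pattern_inhalation = deposition_pattern("inhalation"),
                                 pattern_exhalation = deposition_pattern("exhalation"),
                                 geometry = bifurcation_geometry(),
                                 nuclides = radon_nuclides()) {
  dt <- config$timestep_s
  t0 <- state$time_s
  R <- config$replication
  w <- 1 / R
  chain <- nuclides$name[1:3]
  ph <- if ((t0 %% config$breathing_cycle_s) < config$breathing_cycle_s / 2) {
    "inhalation"
  } else {
    "exhalation"
  }
  if (config$scenario == 1) {
    pattern_inhalation <- deposition_pattern("inhalation", hotspot_weight = 0)
    pattern_exhalation <- deposition_pattern("exhalation", hotspot_weight = 0)
  }
  pat <- if (ph == "inhalation") pattern_inhalation else pattern_exhalation

  p <- state$particles
  # (1) new depositions
  dep <- sources$deposition |> filter(.data$phase == ph)
  for (k in seq_len(nrow(dep))) {
    n <- rpois(1, dep$rate_per_s[k] * dt * R)
    if (n == 0) next
    pos <- sample_deposition_site(n, pat, geometry)
    pos$species <- dep$nuclide[k]
    pos$origin <- "deposited"
    pos$weight <- w
    state$counters$deposited <- state$counters$deposited + n * w
    p <- bind_rows(p, pos)
  }
  # (2) new entries
  if (config$scenario == 3) {
    act <- sources$entry |> filter(.data$ramp_time_s <= t0)
    if (nrow(act) > 0) {
      rates <- act |>
        group_by(.data$nuclide) |>
        summarise(r = sum(.data$rate_per_s), .groups = "drop")
      for (k in seq_len(nrow(rates))) {
        n <- rpois(1, rates$r[k] * dt * R)
        if (n == 0) next
        p <- bind_rows(p, tibble(
          branch = sample(c("daughter_a", "daughter_b"), n, replace = TRUE),
          axial_mm = 0, azimuth_deg = runif(n, 0, 360),
          species = rates$nuclide[k], origin = "entered", weight = w
        ))
        state$counters$entered <- state$counters$entered + n * w
      }
    }
  }
  if (nrow(p) > 0) {
    # (3) motion
    if (config$scenario == 3) {
      if (is.null(p[["trajectory"]])) p$trajectory <- NA_integer_
      need <- is.na(p$trajectory)
      if (any(need)) {
        p$trajectory[need] <- nearest_trajectory(
          trajectories, p$branch[need], p$axial_mm[need], p$azimuth_deg[need]
        )
      }
      newpos <- trajectory_position_after(
        trajectories, p$trajectory, p$branch, p$axial_mm, dt / 60
      )
      at_outlet <- newpos$branch == "parent" &
        newpos$axial_mm >= .branch_length_mm("parent", geometry) - 1e-9
      p$branch <- newpos$branch
      p$axial_mm <- newpos$axial_mm
      p$azimuth_deg <- newpos$azimuth_deg
      state$counters$exited <- state$counters$exited + sum(at_outlet) * w
      p <- p[!at_outlet, ]
    }
  }
  if (nrow(p) > 0) {
    # (4) decay draws
    lam <- setNames(nuclides$decay_constant, nuclides$name)
    dec <- sample_decay(lam[p$species], dt, nrow(p))
    dec[p$species == "pb210"] <- FALSE
    if (any(dec)) {
      alpha <- setNames(nuclides$alpha_energy_MeV, nuclides$name)
      state$events <- bind_rows(state$events, tibble(
        time_s = t0 + dt, species = p$species[dec], branch = p$branch[dec],
        axial_mm = p$axial_mm[dec], azimuth_deg = p$azimuth_deg[dec],
        alpha_energy_MeV = unname(alpha[p$species[dec]]), weight = w
      ))
      p$species[dec] <- transmute_nuclide(p$species[dec], nuclides)
    }
    # (5) terminal nuclei leave radioactive tracking but stay on the wall
  }
  state$particles <- p
  state$time_s <- t0 + dt
  state
}

#' Fresh state for the fixed-step scheme
#'
#' @return list with `time_s = 0`, empty `particles` and `events`, zeroed
#'   `counters`.
#' @export
new_step_state <- function() {
  list(
    time_s = 0,
    particles = tibble(
      branch = character(), axial_mm = numeric(), azimuth_deg = numeric(),
      species = character(), origin = character(), weight = numeric(),
      trajectory = integer()
    ),
    events = tibble(
      time_s = numeric(), species = character(), branch = character(),
      axial_mm = numeric(), azimuth_deg = numeric(),
      alpha_energy_MeV = numeric(), weight = numeric()
    ),
    counters = list(deposited = 0, entered = 0, exited = 0)
  )
}
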