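# Surrogate mucus velocity field over the bifurcation surface and the
# streamline clearance trajectories integrated through it.
#
# The base speed profile conserves mucus volume flux with a constant gel
# film: constant speed along each daughter (the boundary value at the
# daughter inlets), and a perimeter-weighted jump at the daughter->parent
# merge, v_parent = v_daughter * 2 d_daughter / d_parent. A multiplicative
# Gaussian slow zone centred on the carinal ridge reduces the speed locally;
# its depth and extent are shipped calibration constants fitted to the
# residence-time statistics (mean ~20 min, sd ~1.7 min, maximum ~29 min
# over 2,000 inlet-seeded trajectories).

#' Surrogate mucus velocity field
#'
#' @param geometry bifurcation geometry.
#' @param inlet_velocity_mm_min mucus speed at the daughter inlets (boundary
#'   value, default 1 mm/min, derived from 5.5 mm/min in the trachea).
#' @param slow_zone_depth fractional speed reduction at the carinal apex
#'   (0 = no slow zone, 1 = full stop); shipped calibration.
#' @param slow_zone_sigma_mm extent of the slow zone (mm); shipped
#'   calibration.
#' @param slow_zone_shape exponent of the generalised-Gaussian zone profile
#'   (2 = Gaussian); shipped calibration.
#' @param gel_um,sol_um gel / sol layer thicknesses (um).
#' @return list of class `mucus_field`. Metadata records the nominal mucus
#'   density (100 kg/m^3, as configured) and viscosity (1 Pa s); the
#'   kinematic surrogate uses neither.
#' @export
mucus_field <- function(geometry = bifurcation_geometry(),
                        inlet_velocity_mm_min = 1.0,
                        slow_zone_depth = calibrated_defaults()$slow_zone_depth,
                        slow_zone_sigma_mm = calibrated_defaults()$slow_zone_sigma_mm,
                        slow_zone_shape = calibrated_defaults()$slow_zone_shape,
                        gel_um = 5, sol_um = 4) {
  stopifnot(
    inlet_velocity_mm_min > 0, slow_zone_depth >= 0, slow_zone_depth < 1,
    slow_zone_sigma_mm > 0, slow_zone_shape > 0
  )
  structure(
    list(
      geometry = geometry,
      inlet_velocity_mm_min = inlet_velocity_mm_min,
      parent_velocity_mm_min = inlet_velocity_mm_min * 2 *
        geometry$daughter_diameter_cm / geometry$parent_diameter_cm,
      slow_zone_depth = slow_zone_depth,
      slow_zone_sigma_mm = slow_zone_sigma_mm,
      slow_zone_shape = slow_zone_shape,
      gel_um = gel_um, sol_um = sol_um,
      metadata = list(mucus_density_kg_m3 = 100, mucus_viscosity_Pa_s = 1)
    ),
    class = "mucus_field"
  )
}

# slow-zone multiplier in (0, 1]; generalised-Gaussian profile whose shape
# exponent controls how sharply the zone releases trajectories that pass
# close to the ridge (shape 2 = Gaussian)
.slow_zone_factor <- function(field, dist_mm) {
  p <- field$slow_zone_shape
  1 - field$slow_zone_depth *
    exp(-(dist_mm / field$slow_zone_sigma_mm)^p / p)
}

#' Mucus velocity at a surface coordinate
#'
#' Speed is the flux-conserving base profile of the branch times the
#' slow-zone reduction; direction is always towards the parent outlet
#' (+axial in every chart).
#'
#' @param branch,axial_mm,azimuth_deg surface coordinates (vectorised).
#' @param field mucus field, see [mucus_field()].
#' @return tibble with `branch`, `axial_mm`, `azimuth_deg`,
#'   `speed_mm_min`, `direction` (`"to_parent_outlet"`).
#' @export
mucus_velocity_at <- function(branch, axial_mm, azimuth_deg, field = mucus_field()) {
  geometry <- field$geometry
  L <- .branch_length_mm(branch, geometry)
  if (any(axial_mm < 0 | axial_mm > L) ||
    !all(branch %in% c("parent", "daughter_a", "daughter_b"))) {
    abort("coordinate off the bifurcation surface")
  }
  base <- ifelse(branch == "parent", field$parent_velocity_mm_min,
    field$inlet_velocity_mm_min
  )
  dist <- carina_distance_mm(branch, axial_mm, azimuth_deg, geometry)
  tibble(
    branch = branch, axial_mm = axial_mm, azimuth_deg = azimuth_deg %% 360,
    speed_mm_min = base * .slow_zone_factor(field, dist),
    direction = "to_parent_outlet"
  )
}

# first-order streamline time integration along one chart for a *vector* of
# trajectories sharing the same branch type. Returns cumulative time (min)
# on the stored axial grid: matrix [length(ax_store), n].
.integrate_branch <- function(field, branch, azimuth_deg, step_mm, ax_store) {
  geometry <- field$geometry
  L <- .branch_length_mm(branch[1], geometry)
  r <- .branch_radius_mm(branch[1], geometry)
  base <- if (branch[1] == "parent") field$parent_velocity_mm_min else field$inlet_velocity_mm_min
  rad <- pi / 180
  ref <- if (branch[1] == "parent") {
    pmin(.ang_diff(azimuth_deg, 90), .ang_diff(azimuth_deg, 270))
  } else {
    .ang_diff(azimuth_deg, 180)
  }
  arc2 <- (r * ref * rad)^2
  n_step <- ceiling(L / step_mm)
  h <- L / n_step
  tcum <- rep(0, length(azimuth_deg))
  out <- matrix(0, nrow = length(ax_store), ncol = length(azimuth_deg))
  store_idx <- 1L
  if (abs(ax_store[1]) < 1e-12) {
    out[1L, ] <- 0
    store_idx <- 2L
  }
  for (k in seq_len(n_step)) {
    x0 <- (k - 1) * h
    ax_eff <- if (branch[1] == "parent") x0 else L - x0
    v <- base * .slow_zone_factor(field, sqrt(ax_eff^2 + arc2))
    if (any(v <= 1e-9)) abort("mucus speed underflow: streamline cannot terminate")
    tcum <- tcum + h / v
    while (store_idx <= length(ax_store) && ax_store[store_idx] <= k * h + 1e-9) {
      out[store_idx, ] <- tcum - (k * h - ax_store[store_idx]) / v
      store_idx <- store_idx + 1L
    }
  }
  out
}

#' Pre-computed clearance trajectories
#'
#' Integrates `n` surface streamlines from the two daughter inlet
#' circumferences (evenly spaced azimuths, `n/2` per daughter) through the
#' bifurcation to the parent outlet, with a fixed 10 um spatial step.
#' Because the surrogate streamlines keep a constant azimuth within each
#' branch chart, a trajectory is fully described by its starting azimuth,
#' the stitched parent azimuth and the cumulative-time profiles along the
#' two charts; these are stored on a 0.1 mm axial grid for interpolation.
#' Clearance is size-blind: trajectories carry no particle-diameter
#' dependence at all.
#'
#' @param n number of trajectories (split evenly between the daughters).
#' @param field mucus field.
#' @param step_mm integration step (mm).
#' @param store_mm storage grid spacing (mm).
#' @return list of class `trajectory_set`: `info` tibble (`id`, `branch`,
#'   `azimuth_daughter_deg`, `azimuth_parent_deg`, `residence_min`), axial
#'   grids `ax_d`, `ax_p` and cumulative-time matrices `ct_d`, `ct_p`
#'   (minutes since the daughter inlet).
#' @export
clearance_trajectories <- function(n = 2000, field = mucus_field(),
                                   step_mm = 0.01, store_mm = 0.1) {
  stopifnot(n >= 2, n %% 2 == 0)
  geometry <- field$geometry
  L_d <- .branch_length_mm("daughter_a", geometry)
  L_p <- .branch_length_mm("parent", geometry)
  half <- n / 2
  az_d <- (seq_len(half) - 0.5) * 360 / half
  branch <- rep(c("daughter_a", "daughter_b"), each = half)
  az_all <- c(az_d, az_d)
  az_p <- stitch_azimuth(branch, az_all)

  ax_d <- seq(0, L_d, by = store_mm)
  if (ax_d[length(ax_d)] < L_d - 1e-9) ax_d <- c(ax_d, L_d)
  ax_p <- seq(0, L_p, by = store_mm)
  if (ax_p[length(ax_p)] < L_p - 1e-9) ax_p <- c(ax_p, L_p)

  ct_d <- .integrate_branch(field, rep("daughter_a", n), az_all, step_mm, ax_d)
  t_junction <- ct_d[nrow(ct_d), ]
  ct_p <- .integrate_branch(field, rep("parent", n), az_p, step_mm, ax_p)
  ct_p <- sweep(ct_p, 2, t_junction, `+`)

  info <- tibble(
    id = seq_len(n), branch = branch,
    azimuth_daughter_deg = az_all, azimuth_parent_deg = az_p,
    residence_min = ct_p[nrow(ct_p), ]
  )
  structure(
    list(
      info = info, ax_d = ax_d, ax_p = ax_p, ct_d = ct_d, ct_p = ct_p,
      field = field
    ),
    class = "trajectory_set"
  )
}

#' Trace a single clearance trajectory
#'
#' Integrates the surface streamline from an arbitrary start point to the
#' parent outlet and returns the ordered path with per-segment transit
#' times.
#'
#' @param branch,axial_mm,azimuth_deg start coordinate.
#' @param field mucus field.
#' @param step_mm integration step (mm).
#' @param store_mm output sampling (mm).
#' @return tibble of class `clearance_trajectory`: ordered surface
#'   coordinates with cumulative `time_min`; the final row is the parent
#'   outlet and its `time_min` is the total residence time.
#' @export
trace_trajectory <- function(branch, axial_mm, azimuth_deg,
                             field = mucus_field(), step_mm = 0.01,
                             store_mm = 0.1) {
  geometry <- field$geometry
  L <- .branch_length_mm(branch, geometry)
  if (axial_mm < 0 || axial_mm > L) abort("start coordinate off the surface")
  segs <- list()
  t0 <- 0
  if (branch != "parent") {
    L_d <- .branch_length_mm(branch, geometry)
    ax <- seq(axial_mm, L_d, by = store_mm)
    if (ax[length(ax)] < L_d - 1e-9) ax <- c(ax, L_d)
    ct <- .integrate_partial(field, branch, azimuth_deg, axial_mm, ax, step_mm)
    segs[[1]] <- tibble(
      branch = branch, axial_mm = ax, azimuth_deg = azimuth_deg %% 360,
      time_min = ct
    )
    t0 <- ct[length(ct)]
    azimuth_deg <- stitch_azimuth(branch, azimuth_deg)
    axial_mm <- 0
    branch <- "parent"
  }
  L_p <- .branch_length_mm("parent", geometry)
  ax <- seq(axial_mm, L_p, by = store_mm)
  if (ax[length(ax)] < L_p - 1e-9) ax <- c(ax, L_p)
  ct <- .integrate_partial(field, "parent", azimuth_deg, axial_mm, ax, step_mm)
  segs[[length(segs) + 1]] <- tibble(
    branch = "parent", axial_mm = ax, azimuth_deg = azimuth_deg %% 360,
    time_min = t0 + ct
  )
  out <- bind_rows(segs)
  class(out) <- c("clearance_trajectory", class(out))
  out
}

# cumulative time from ax_start to each ax in `ax_out` (all >= ax_start)
.integrate_partial <- function(field, branch, azimuth_deg, ax_start, ax_out,
                               step_mm) {
  geometry <- field$geometry
  L <- .branch_length_mm(branch, geometry)
  r <- .branch_radius_mm(branch, geometry)
  base <- if (branch == "parent") field$parent_velocity_mm_min else field$inlet_velocity_mm_min
  rad <- pi / 180
  ref <- if (branch == "parent") {
    min(.ang_diff(azimuth_deg, 90), .ang_diff(azimuth_deg, 270))
  } else {
    .ang_diff(azimuth_deg, 180)
  }
  arc2 <- (r * ref * rad)^2
  span <- L - ax_start
  n_step <- max(1L, ceiling(span / step_mm))
  h <- span / n_step
  tcum <- 0
  out <- numeric(length(ax_out))
  idx <- 1L
  while (idx <= length(ax_out) && ax_out[idx] <= ax_start + 1e-9) {
    out[idx] <- 0
    idx <- idx + 1L
  }
  for (k in seq_len(n_step)) {
    x0 <- ax_start + (k - 1) * h
    ax_eff <- if (branch == "parent") x0 else L - x0
    v <- base * .slow_zone_factor(field, sqrt(ax_eff^2 + arc2))
    if (v <= 1e-9) abort("mucus speed underflow: streamline cannot terminate")
    tcum <- tcum + h / v
    while (idx <= length(ax_out) && ax_out[idx] <= ax_start + k * h + 1e-9) {
      out[idx] <- tcum - (ax_start + k * h - ax_out[idx]) / v
      idx <- idx + 1L
    }
  }
  out
}

#' Nearest pre-computed trajectory for a surface point
#'
#' Resolves "nearest at the moment of deposition" by arc distance in the
#' (branch, axial, azimuth) chart. Because trajectories hold their azimuth
#' within a chart and cover every axial position, the nearest trajectory is
#' the one with the smallest azimuthal arc distance in the point's chart;
#' ties break to the lowest trajectory id.
#'
#' @param trajectories `trajectory_set`.
#' @param branch,axial_mm,azimuth_deg surface point(s).
#' @return integer vector of trajectory ids.
#' @export
nearest_trajectory <- function(trajectories, branch, axial_mm, azimuth_deg) {
  info <- trajectories$info
  n <- length(branch)
  ids <- integer(n)
  # candidate azimuths per chart; nearest found on the sorted circle
  nearest_on_circle <- function(cand_az, cand_id, az) {
    o <- order(cand_az, cand_id)
    ca <- cand_az[o]
    ci <- cand_id[o]
    m <- length(ca)
    pos <- findInterval(az %% 360, ca)
    lo <- ifelse(pos == 0, m, pos)
    hi <- ifelse(pos == m, 1, pos + 1)
    d_lo <- .ang_diff(ca[lo], az)
    d_hi <- .ang_diff(ca[hi], az)
    # ties (equal arc distance) resolve to the lower id
    pick_lo <- d_lo < d_hi | (d_lo == d_hi & ci[lo] < ci[hi])
    ifelse(pick_lo, ci[lo], ci[hi])
  }
  for (br in unique(branch)) {
    sel <- branch == br
    if (br == "parent") {
      ids[sel] <- nearest_on_circle(
        info$azimuth_parent_deg, info$id, azimuth_deg[sel]
      )
    } else {
      cand <- info[info$branch == br, ]
      ids[sel] <- nearest_on_circle(
        cand$azimuth_daughter_deg, cand$id, azimuth_deg[sel]
      )
    }
  }
  ids
}

# linear interpolation of per-trajectory columns on a uniform axial grid,
# vectorised over (id, x) pairs
.interp_traj <- function(grid, mat, id, x) {
  h <- grid[2] - grid[1]
  i <- pmin(pmax(floor(x / h), 0), length(grid) - 2)
  frac <- pmin(pmax((x - i * h) / h, 0), 1)
  lo <- mat[cbind(i + 1, id)]
  hi <- mat[cbind(i + 2, id)]
  lo + frac * (hi - lo)
}

# time (min since daughter inlet) at which trajectory `id` passes
# (branch, axial); vectorised over points
.trajectory_clock_at <- function(trajectories, id, branch, axial_mm) {
  out <- numeric(length(id))
  is_par <- branch == "parent"
  if (any(!is_par)) {
    sel <- !is_par
    out[sel] <- .interp_traj(
      trajectories$ax_d, trajectories$ct_d, id[sel], axial_mm[sel]
    )
  }
  if (any(is_par)) {
    out[is_par] <- .interp_traj(
      trajectories$ax_p, trajectories$ct_p, id[is_par], axial_mm[is_par]
    )
  }
  out
}

#' Remaining residence time from a surface point
#'
#' Time (min) a particle sitting at the given point needs to reach the
#' parent outlet along its assigned trajectory.
#'
#' @param trajectories `trajectory_set`.
#' @param id trajectory ids (from [nearest_trajectory()]).
#' @param branch,axial_mm point coordinates.
#' @return numeric vector (min).
#' @export
trajectory_time_remaining <- function(trajectories, id, branch, axial_mm) {
  total <- trajectories$info$residence_min[id]
  total - .trajectory_clock_at(trajectories, id, branch, axial_mm)
}

#' Position along a trajectory after an elapsed time
#'
#' @param trajectories `trajectory_set`.
#' @param id trajectory ids.
#' @param branch,axial_mm current coordinates.
#' @param elapsed_min elapsed times (min).
#' @return tibble `branch`, `axial_mm`, `azimuth_deg` of the advanced
#'   positions (points that pass the outlet are clamped to it).
#' @export
trajectory_position_after <- function(trajectories, id, branch, axial_mm,
                                      elapsed_min) {
  clock <- .trajectory_clock_at(trajectories, id, branch, axial_mm) + elapsed_min
  n <- length(id)
  out_branch <- character(n)
  out_ax <- numeric(n)
  out_az <- numeric(n)
  info <- trajectories$info
  for (k in seq_len(n)) {
    i <- id[k]
    t_junction <- trajectories$ct_d[nrow(trajectories$ct_d), i]
    if (clock[k] <= t_junction && branch[k] != "parent") {
      out_branch[k] <- info$branch[i]
      out_ax[k] <- approx(trajectories$ct_d[, i], trajectories$ax_d,
        xout = clock[k], rule = 2
      )$y
      out_az[k] <- info$azimuth_daughter_deg[i]
    } else {
      out_branch[k] <- "parent"
      out_ax[k] <- approx(trajectories$ct_p[, i], trajectories$ax_p,
        xout = clock[k], rule = 2
      )$y
      out_az[k] <- info$azimuth_parent_deg[i]
    }
  }
  tibble(branch = out_branch, axial_mm = out_ax, azimuth_deg = out_az)
}

#' Residence-time summary of a trajectory set
#'
#' @param trajectories `trajectory_set`.
#' @return one-row tibble: `n`, `mean_min`, `sd_min`, `max_min`, `min_min`.
#' @export
residence_summary <- function(trajectories) {
  r <- trajectories$info$residence_min
  tibble(
    n = length(r), mean_min = mean(r), sd_min = stats::sd(r),
    max_min = max(r), min_min = min(r)
  )
}
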