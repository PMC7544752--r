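# Alpha-track microdosimetry: continuous-slowing-down energy loss through
# mucus (gel + sol), air (far-wall lumen crossings) and epithelial tissue,
# analytic ray-ellipsoid chords through basal and secretory cell nuclei,
# and the resulting nucleus doses.

# Bragg-Kleeman power-law fit R(E) = k E^p anchored at the standard alpha
# CSDA ranges in soft tissue (48 um at 6 MeV, 71 um at 7.69 MeV) and air
# (4.6 cm at 6 MeV); mucus is treated as tissue-equivalent.  Both media
# share the exponent, so an air path converts to a tissue-equivalent path
# by the constant factor k_tissue/k_air.
.BK_P <- log(71 / 48) / log(7.69 / 6)
.BK_K_TISSUE <- 48 / 6^.BK_P # um / MeV^p
.BK_K_AIR <- 4.6e4 / 6^.BK_P

#' Alpha stopping-power and range table
#'
#' Packaged numeric table of stopping power (MeV/um) and CSDA range (um)
#' for alpha particles in air and in soft tissue (mucus is treated as
#' tissue-equivalent), generated from a Bragg-Kleeman power-law range fit
#' anchored at the standard tissue ranges of the 6.0 and 7.69 MeV radon
#' progeny alphas (48 um and 71 um) and the 6 MeV range in air (4.6 cm).
#' The table is the exchangeable interface: any (energy, stopping power)
#' grid with the same columns can be substituted.
#'
#' @param energies_MeV energy grid.
#' @return tibble `energy_MeV`, `S_tissue_MeV_um`, `S_air_MeV_um`,
#'   `range_tissue_um`, `range_air_um`.
#' @export
stopping_power_table <- function(energies_MeV = seq(0.05, 8, by = 0.05)) {
  stopifnot(all(energies_MeV > 0))
  E <- energies_MeV
  tibble(
    energy_MeV = E,
    S_tissue_MeV_um = E^(1 - .BK_P) / (.BK_K_TISSUE * .BK_P),
    S_air_MeV_um = E^(1 - .BK_P) / (.BK_K_AIR * .BK_P),
    range_tissue_um = .BK_K_TISSUE * E^.BK_P,
    range_air_um = .BK_K_AIR * E^.BK_P
  )
}

#' CSDA range and its inverse
#'
#' Monotone interpolation on a stopping-power table.
#'
#' @param energy_MeV energies (MeV).
#' @param medium `"tissue"` or `"air"`.
#' @param table stopping-power table.
#' @return `csda_range_um()`: range (um); `energy_at_range_um()`: energy
#'   (MeV) whose range equals the given value (0 below the grid).
#' @export
csda_range_um <- function(energy_MeV, medium = c("tissue", "air"),
                          table = stopping_power_table()) {
  medium <- match.arg(medium)
  col <- if (medium == "tissue") table$range_tissue_um else table$range_air_um
  if (any(energy_MeV > max(table$energy_MeV) + 1e-9)) {
    abort("energy grid does not cover the requested energy")
  }
  approx(table$energy_MeV, col, xout = energy_MeV, rule = 2)$y
}

#' @rdname csda_range_um
#' @param range_um residual ranges (um).
#' @export
energy_at_range_um <- function(range_um, medium = c("tissue", "air"),
                               table = stopping_power_table()) {
  medium <- match.arg(medium)
  col <- if (medium == "tissue") table$range_tissue_um else table$range_air_um
  out <- approx(col, table$energy_MeV, xout = range_um, rule = 2)$y
  out[range_um <= min(col)] <- 0
  out
}

#' Energy profile along a multi-medium track
#'
#' Continuous-slowing-down integration: cumulative tissue-equivalent depth
#' is accumulated segment by segment (air scaled by the range ratio), and
#' the residual energy follows from the inverse range function.
#'
#' @param segments tibble with `medium` (`"tissue"`/`"mucus"`/`"air"`) and
#'   `length_um`, in track order.
#' @param energy_MeV initial energy.
#' @param table stopping-power table.
#' @return the segments tibble with `energy_in_MeV`, `energy_out_MeV` and
#'   `deposited_MeV` per segment (clamped when the track ends inside a
#'   segment).
#' @export
energy_along_track <- function(segments, energy_MeV,
                               table = stopping_power_table()) {
  if (any(!segments$medium %in% c("tissue", "mucus", "air"))) {
    abort("unknown medium")
  }
  r0 <- csda_range_um(energy_MeV, "tissue", table)
  scale <- ifelse(segments$medium == "air",
    csda_range_um(energy_MeV, "tissue", table) /
      csda_range_um(energy_MeV, "air", table),
    1
  )
  te <- cumsum(segments$length_um * scale)
  r_in <- pmax(r0 - c(0, head(te, -1)), 0)
  r_out <- pmax(r0 - te, 0)
  e_in <- energy_at_range_um(r_in, "tissue", table)
  e_out <- energy_at_range_um(r_out, "tissue", table)
  segments |>
    mutate(
      energy_in_MeV = e_in, energy_out_MeV = e_out,
      deposited_MeV = e_in - e_out
    )
}

#' Epithelium model: ellipsoidal cell-nucleus population
#'
#' Parameters of the two radiosensitive target populations of the
#' bronchial epithelium. Depth is the nucleus centre below the sol-tissue
#' interface; nuclei are ellipsoids with semi-axes `(ax, ay, az)` (um),
#' z vertical. The overlying gel (5 um) and sol (4 um) only attenuate the
#' alpha energy. The defaults are literature-derived morphometric values
#' for human central bronchi (oblique-section caveats make the depth
#' distributions the most uncertain input; all values are configuration).
#'
#' @param types tibble overriding the default population table (columns
#'   `type`, `density_mm2`, `depth_min_um`, `depth_max_um`, `ax_um`,
#'   `ay_um`, `az_um`).
#' @param gel_um,sol_um mucus sublayer thicknesses (um).
#' @param tissue_density_kg_m3 tissue density.
#' @return list of class `epithelium_model`.
#' @export
epithelium_model <- function(types = NULL, gel_um = 5, sol_um = 4,
                             tissue_density_kg_m3 = 1000) {
  types <- types %||% tibble(
    type = c("secretory", "basal"),
    density_mm2 = c(800, 600),
    depth_min_um = c(10, 35),
    depth_max_um = c(40, 50),
    ax_um = c(4, 3.5), ay_um = c(3, 2.5), az_um = c(3, 2.5)
  )
  stopifnot(all(types$depth_min_um >= 0), all(types$depth_max_um > types$depth_min_um))
  structure(
    list(
      types = types, gel_um = gel_um, sol_um = sol_um,
      tissue_density_kg_m3 = tissue_density_kg_m3
    ),
    class = "epithelium_model"
  )
}

#' Sample a non-overlapping nucleus population on a tile
#'
#' Draws nucleus centres uniformly over a rectangular tile, depths from the
#' type-specific distributions, and rejects candidates overlapping an
#' already-placed nucleus (centre distance below the sum of the two
#' maximal semi-axes).
#'
#' @param epithelium `epithelium_model`.
#' @param tile_mm half-widths are `tile_mm/2`: the tile spans
#'   `[-tile_mm/2, tile_mm/2]^2` (mm) in local surface coordinates.
#' @param max_attempts rejection-sampling cap per nucleus.
#' @return tibble: `nucleus_id`, `type`, `x_um`, `y_um`, `depth_um`,
#'   `ax_um`, `ay_um`, `az_um`, `mass_kg`.
#' @export
sample_nuclei <- function(epithelium = epithelium_model(), tile_mm = 1,
                          max_attempts = 200) {
  half_um <- tile_mm * 1000 / 2
  out <- list()
  placed_x <- numeric(0)
  placed_y <- numeric(0)
  placed_z <- numeric(0)
  placed_r <- numeric(0)
  for (k in seq_len(nrow(epithelium$types))) {
    ty <- epithelium$types[k, ]
    n <- rpois(1, ty$density_mm2 * tile_mm^2)
    if (n == 0) next
    rmax <- max(ty$ax_um, ty$ay_um, ty$az_um)
    xs <- numeric(n); ys <- numeric(n); zs <- numeric(n)
    for (i in seq_len(n)) {
      for (att in seq_len(max_attempts)) {
        x <- runif(1, -half_um, half_um)
        y <- runif(1, -half_um, half_um)
        z <- runif(1, ty$depth_min_um, ty$depth_max_um)
        if (length(placed_x) == 0 ||
          all((placed_x - x)^2 + (placed_y - y)^2 + (placed_z - z)^2 >
            (placed_r + rmax)^2)) {
          break
        }
      }
      xs[i] <- x; ys[i] <- y; zs[i] <- z
      placed_x <- c(placed_x, x); placed_y <- c(placed_y, y)
      placed_z <- c(placed_z, z); placed_r <- c(placed_r, rmax)
    }
    out[[k]] <- tibble(
      type = ty$type, x_um = xs, y_um = ys, depth_um = zs,
      ax_um = ty$ax_um, ay_um = ty$ay_um, az_um = ty$az_um
    )
  }
  nuc <- bind_rows(out)
  if (nrow(nuc) == 0) {
    return(tibble(
      nucleus_id = integer(), type = character(), x_um = numeric(),
      y_um = numeric(), depth_um = numeric(), ax_um = numeric(),
      ay_um = numeric(), az_um = numeric(), mass_kg = numeric()
    ))
  }
  nuc$nucleus_id <- seq_len(nrow(nuc))
  nuc$mass_kg <- 4 / 3 * pi * nuc$ax_um * nuc$ay_um * nuc$az_um * 1e-18 *
    epithelium$tissue_density_kg_m3
  select(
    nuc, "nucleus_id", "type", "x_um", "y_um", "depth_um",
    "ax_um", "ay_um", "az_um", "mass_kg"
  )
}

#' Ray-ellipsoid chord
#'
#' Entry and exit path lengths of a ray through an axis-aligned ellipsoid,
#' from the closed-form quadratic.
#'
#' @param origin numeric length-3 ray origin.
#' @param direction unit direction.
#' @param center ellipsoid centre.
#' @param semi_axes numeric length-3.
#' @return `c(s_in, s_out)` path lengths (`NA`s when the ray misses; only
#'   the forward part of the ray counts).
#' @export
ray_ellipsoid_chord <- function(origin, direction, center, semi_axes) {
  o <- (origin - center) / semi_axes
  d <- direction / semi_axes
  a <- sum(d^2)
  b <- 2 * sum(o * d)
  cc <- sum(o^2) - 1
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) {
    return(c(NA_real_, NA_real_))
  }
  sq <- sqrt(disc)
  s1 <- (-b - sq) / (2 * a)
  s2 <- (-b + sq) / (2 * a)
  if (s2 <= 0) {
    return(c(NA_real_, NA_real_))
  }
  c(max(s1, 0), s2)
}

# vectorised over nuclei: chords of one ray through many ellipsoids;
# returns matrix [n, 2] of (s_in, s_out)
.ray_chords <- function(origin, direction, cx, cy, cz, ax, ay, az) {
  ox <- (origin[1] - cx) / ax
  oy <- (origin[2] - cy) / ay
  oz <- (origin[3] - cz) / az
  dx <- direction[1] / ax
  dy <- direction[2] / ay
  dz <- direction[3] / az
  a <- dx^2 + dy^2 + dz^2
  b <- 2 * (ox * dx + oy * dy + oz * dz)
  cc <- ox^2 + oy^2 + oz^2 - 1
  disc <- b^2 - 4 * a * cc
  hit <- disc > 0
  s1 <- s2 <- rep(NA_real_, length(cx))
  if (any(hit)) {
    sq <- sqrt(disc[hit])
    s1[hit] <- (-b[hit] - sq) / (2 * a[hit])
    s2[hit] <- (-b[hit] + sq) / (2 * a[hit])
    bad <- !is.na(s2) & s2 <= 0
    s1[bad] <- NA_real_
    s2[bad] <- NA_real_
    s1 <- pmax(s1, 0)
  }
  cbind(s1, s2)
}

#' Isotropic unit directions
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors uniform on the sphere.
#' @export
isotropic_directions <- function(n) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# random lumen chord (um) for a far-wall track leaving the wall of a tube
# of diameter d_cm at upward angle; transverse geometry of a circle:
# chord3d = 2 r cos(psi) / |u_t| * ... computed exactly in the transverse
# plane. `u` is the direction in local coordinates with +z away from the
# wall into the lumen.
.lumen_chord_um <- function(u, diameter_cm) {
  r_um <- diameter_cm / 2 * 1e4
  ut <- sqrt(u[, 1]^2 + u[, 3]^2) # transverse = (horizontal-x, vertical-z)
  # in the transverse plane the inward normal is +z; cos(psi) between the
  # transverse direction and the inward normal:
  cospsi <- pmax(u[, 3] / pmax(ut, 1e-12), 0)
  chord2d <- 2 * r_um * cospsi
  chord2d / pmax(ut, 1e-12) * 1 # path length whose transverse advance is chord2d
}

#' Nucleus doses from a set of alpha decay events
#'
#' Local-frame (flat-patch) microdosimetry over one analysis tile: events
#' carry positions in the tile's local coordinates (mm) and statistical
#' weights; for every event `n_tracks_per_event` isotropic alpha tracks
#' with weight `weight/n_tracks_per_event` are generated. Downward tracks
#' (into the wall) deposit energy in the remaining gel + sol mucus and
#' then in tissue (near-wall). Upward tracks leave across the lumen and
#' land far from the tile; conversely, far-wall tracks arriving at the
#' tile are generated from the surface-averaged event rate
#' (`background_rate_per_mm2`, alpha events per mm^2 of wall over the same
#' exposure, with the same energy mix), each attenuated by a random lumen
#' chord of the local airway before reaching the tile. Curvature is
#' neglected at the 100 um scale of a tile (flat-patch approximation).
#'
#' @param events tibble: `x_mm`, `y_mm`, `energy_MeV`, `weight`.
#' @param nuclei tibble from [sample_nuclei()].
#' @param epithelium `epithelium_model`.
#' @param table stopping-power table.
#' @param n_tracks_per_event track multiplicity per event (variance
#'   reduction; weights scaled by `1/n`).
#' @param tile_mm tile edge (events and nuclei live on
#'   `[-tile_mm/2, tile_mm/2]^2`).
#' @param background_rate_per_mm2 surface-average alpha areal density for
#'   the far-wall arrival source; `NULL` disables far-wall arrivals.
#' @param background_energy_MeV energies to sample far-wall arrivals from
#'   (resampled with replacement); defaults to the event energies.
#' @param lumen_diameter_cm local airway diameter for the lumen chord.
#' @param emission_depth_um emission depth inside the gel layer (default:
#'   gel mid-depth).
#' @return `nuclei` with added `dose_Gy`, `energy_MeV`, `hits` (weighted).
#' @export
nucleus_doses <- function(events, nuclei, epithelium = epithelium_model(),
                          table = stopping_power_table(),
                          n_tracks_per_event = 1, tile_mm = 1,
                          background_rate_per_mm2 = NULL,
                          background_energy_MeV = NULL,
                          lumen_diameter_cm = 0.45,
                          emission_depth_um = NULL) {
  emission_depth_um <- emission_depth_um %||% (epithelium$gel_um / 2)
  mucus_um <- epithelium$gel_um + epithelium$sol_um
  n_nuc <- nrow(nuclei)
  dose <- numeric(n_nuc)
  ener <- numeric(n_nuc)
  hits <- numeric(n_nuc)
  if (n_nuc == 0) {
    return(mutate(nuclei, dose_Gy = numeric(0), energy_MeV = numeric(0), hits = numeric(0)))
  }
  # z axis: 0 at the sol-tissue interface, negative up into mucus/lumen;
  # nucleus centres at z = depth
  reach_um <- csda_range_um(max(
    c(events$energy_MeV, background_energy_MeV, 7.69)
  ), "tissue", table)

  run_tracks <- function(x_um, y_um, dirs, e0, w, extra_mucus_um) {
    # `dirs` rows must point into the wall (z > 0 component)
    for (i in seq_along(e0)) {
      u <- dirs[i, ]
      # mucus slant path before tissue
      slant <- (mucus_um - emission_depth_um + extra_mucus_um[i]) / u[3]
      r0 <- csda_range_um(e0[i], "tissue", table)
      r_tissue <- r0 - slant # residual tissue-equivalent range at interface
      if (r_tissue <= 0) next
      e_surf <- energy_at_range_um(r_tissue, "tissue", table)
      # cheap horizontal prefilter
      near <- which(
        abs(nuclei$x_um - x_um[i]) < reach_um + nuclei$ax_um &
          abs(nuclei$y_um - y_um[i]) < reach_um + nuclei$ay_um
      )
      if (length(near) == 0) next
      ch <- .ray_chords(
        c(x_um[i], y_um[i], 0), u,
        nuclei$x_um[near], nuclei$y_um[near], nuclei$depth_um[near],
        nuclei$ax_um[near], nuclei$ay_um[near], nuclei$az_um[near]
      )
      hit <- which(!is.na(ch[, 1]))
      if (length(hit) == 0) next
      s_in <- ch[hit, 1]
      s_out <- ch[hit, 2]
      e_in <- energy_at_range_um(pmax(r_tissue - s_in, 0), "tissue", table)
      e_out <- energy_at_range_um(pmax(r_tissue - s_out, 0), "tissue", table)
      dep <- (e_in - e_out) * w[i]
      idx <- near[hit]
      keep <- dep > 0
      if (any(keep)) {
        ener[idx[keep]] <<- ener[idx[keep]] + dep[keep]
        hits[idx[keep]] <<- hits[idx[keep]] + w[i] * (e_in[keep] > 0)
      }
    }
  }

  # --- near-wall tracks from local events
  if (nrow(events) > 0 && n_tracks_per_event > 0) {
    m <- nrow(events) * n_tracks_per_event
    dirs <- isotropic_directions(m)
    ev_i <- rep(seq_len(nrow(events)), each = n_tracks_per_event)
    down <- dirs[, 3] < 0
    if (any(down)) {
      d <- dirs[down, , drop = FALSE]
      d[, 3] <- -d[, 3] # express as into-the-wall (+z = deeper)
      run_tracks(
        events$x_mm[ev_i[down]] * 1000, events$y_mm[ev_i[down]] * 1000,
        d, events$energy_MeV[ev_i[down]],
        events$weight[ev_i[down]] / n_tracks_per_event,
        extra_mucus_um = rep(0, sum(down))
      )
    }
  }

  # --- far-wall arrivals from the surface-averaged source
  if (!is.null(background_rate_per_mm2) && background_rate_per_mm2 > 0) {
    e_pool <- background_energy_MeV %||% events$energy_MeV
    if (length(e_pool) > 0) {
      # upward hemisphere share of isotropic emission is 1/2
      n_far <- rpois(1, background_rate_per_mm2 * tile_mm^2 / 2 *
        n_tracks_per_event)
      if (n_far > 0) {
        dirs <- isotropic_directions(n_far)
        dirs[, 3] <- abs(dirs[, 3]) # arriving: into the wall
        chord <- .lumen_chord_um(
          cbind(dirs[, 1], dirs[, 2], dirs[, 3]), lumen_diameter_cm
        )
        e0 <- sample(e_pool, n_far, replace = TRUE)
        # degrade through source-side mucus + air chord before our tile
        r0 <- csda_range_um(e0, "tissue", table)
        scale_air <- .BK_K_TISSUE / .BK_K_AIR
        r_left <- r0 - emission_depth_um / dirs[, 3] - chord * scale_air
        live <- r_left > 0
        if (any(live)) {
          e_arr <- energy_at_range_um(r_left[live], "tissue", table)
          run_tracks(
            runif(sum(live), -tile_mm * 500, tile_mm * 500),
            runif(sum(live), -tile_mm * 500, tile_mm * 500),
            dirs[live, , drop = FALSE], e_arr,
            rep(1 / n_tracks_per_event, sum(live)),
            # arriving tracks still have the full gel+sol of our wall ahead;
            # run_tracks adds (mucus - emission_depth), so top up the rest
            extra_mucus_um = rep(emission_depth_um, sum(live))
          )
        }
      }
    }
  }

  nuclei |>
    mutate(
      energy_MeV = ener,
      dose_Gy = ener * MEV_TO_J / .data$mass_kg,
      hits = hits
    )
}
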