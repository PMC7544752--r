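# Independent oracle implementations used to cross-check the package's
# closed-form and event-driven machinery. All oracles are deliberately
# written with different methods than the implementations they test.

# decay constants of the default chain (1/s)
oracle_lambda <- function() {
  log(2) / c(po218 = 183, pb214 = 1608, bi214 = 1182)
}

# ODE oracle for the three-member chain (deSolve, stiff-capable lsoda);
# returns counts at times `t` for initial state `n0`
oracle_chain_ode <- function(n0, t, lambda = oracle_lambda()) {
  rhs <- function(t, y, parms) {
    l <- parms
    list(c(
      -l[1] * y[1],
      l[1] * y[1] - l[2] * y[2],
      l[2] * y[2] - l[3] * y[3]
    ))
  }
  out <- deSolve::ode(
    y = unname(n0), times = c(0, t), func = rhs, parms = unname(lambda),
    rtol = 1e-10, atol = 1e-12
  )
  unname(out[-1, 2:4, drop = FALSE])
}

# per-nucleus Monte Carlo oracle: counts of each species still present
# after time `t`, starting from `n` nuclei of species index `start`
oracle_chain_mc <- function(n, start, t, lambda = oracle_lambda()) {
  acc <- numeric(n)
  species <- rep(4L, n) # 4 = terminal
  alive <- rep(TRUE, n)
  for (k in start:3) {
    acc[alive] <- acc[alive] + rexp(sum(alive), rate = lambda[k])
    now <- alive & acc > t
    species[now] <- k
    alive <- alive & !now
  }
  c(
    sum(species == 1L), sum(species == 2L), sum(species == 3L),
    sum(species == 4L)
  )
}

# Random-walk oracle for diffusional deposition from laminar (parabolic)
# flow in a cylindrical tube. Nondimensional: tube radius 1, mean axial
# speed 1, tube length `L`; particle diffusivity `D` (in units of
# radius * mean-speed). Returns the deposited fraction of `n` particles
# entering with the flow-weighted radial profile.
oracle_tube_diffusion_mc <- function(D, L, n = 4000, dt = NULL) {
  if (is.null(dt)) dt <- min(0.002 / D, 0.05 * L)
  # flow-weighted inlet radius: pdf ~ r (1 - r^2)
  u <- runif(n)
  r2 <- 1 - sqrt(1 - u) # CDF inversion for flow weighting in r^2
  r <- sqrt(r2)
  th <- runif(n, 0, 2 * pi)
  x <- r * cos(th)
  y <- r * sin(th)
  z <- numeric(n)
  active <- rep(TRUE, n)
  deposited <- 0L
  s <- sqrt(2 * D * dt)
  while (any(active)) {
    i <- which(active)
    vz <- 2 * (1 - (x[i]^2 + y[i]^2))
    x[i] <- x[i] + rnorm(length(i), 0, s)
    y[i] <- y[i] + rnorm(length(i), 0, s)
    z[i] <- z[i] + vz * dt
    hit <- x[i]^2 + y[i]^2 >= 1
    out <- z[i] >= L & !hit
    deposited <- deposited + sum(hit)
    active[i[hit | out]] <- FALSE
  }
  deposited / n
}

# deterministic alpha range check: Bragg-Kleeman R = k E^p through two
# anchors computed from first principles (independent of the package's
# internal constants)
oracle_bk_range_um <- function(E) {
  p <- log(71 / 48) / log(7.69 / 6)
  k <- 48 / 6^p
  k * E^p
}

# default sim sources scaled for fast engine-agreement tests: synthetic
# constant deposition rates, no entries
synthetic_sources <- function(rate_per_s = 0.5) {
  structure(
    list(
      deposition = tidyr::expand_grid(
        nuclide = c("po218", "pb214", "bi214"),
        phase = c("inhalation", "exhalation")
      ) |>
        dplyr::mutate(rate_per_s = rate_per_s),
      entry = tibble::tibble(
        nuclide = character(), source_generation = integer(),
        rate_per_s = numeric(), ramp_time_s = numeric()
      )
    ),
    class = "bif_sources"
  )
}
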