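# Closed-form Bateman solutions for the three-member radon progeny chain and
# the per-nucleus stochastic counterpart used by the dynamic simulation.

# (exp(-a t) - exp(-b t)) / (b - a), the first divided difference of
# exp(-x t), with a series fallback when a and b nearly collide.  Always
# >= 0 for t >= 0.  Vectorised over t.
.ediff1 <- function(a, b, t, rel_tol = 1e-9) {
  if (abs(b - a) < rel_tol * max(abs(a), abs(b))) {
    d <- b - a
    # exp(-a t) * t * (1 - d t / 2 + (d t)^2 / 6)
    exp(-a * t) * t * (1 - d * t / 2 + (d * t)^2 / 6)
  } else {
    (exp(-a * t) - exp(-b * t)) / (b - a)
  }
}

# (ediff1(l1, l3) - ediff1(l2, l3)) / (l2 - l1): second divided difference,
# needed by the grand-daughter solution.  Series fallback when l1 ~ l2.
.ediff2 <- function(l1, l2, l3, t, rel_tol = 1e-9) {
  if (abs(l2 - l1) < rel_tol * max(abs(l1), abs(l2))) {
    # limit l2 -> l1 of (g(l1) - g(l2))/(l2 - l1) = -dg/dl at l1,
    # g(l) = ediff1(l, l3, t); use a symmetric numeric derivative on a
    # relative step well above the collision threshold
    h <- max(abs(l1), 1e-300) * 1e-6
    -(.ediff1(l1 + h, l3, t, rel_tol) - .ediff1(l1 - h, l3, t, rel_tol)) / (2 * h)
  } else {
    (.ediff1(l1, l3, t, rel_tol) - .ediff1(l2, l3, t, rel_tol)) / (l2 - l1)
  }
}

#' Evolve a three-member decay chain state (Bateman solution)
#'
#' Deterministic (expected-count) evolution of the nuclide counts
#' `(N1, N2, N3)` of the Po-218 -> Pb-214 -> Bi-214/Po-214 chain over a time
#' `t`, by the closed-form Bateman solution of the chain ODEs. Fractional
#' counts are allowed: these are expectations, not integer nuclei. Near-equal
#' decay constants (relative difference below `1e-9`) are routed to an
#' analytic series limit so the expression stays well-conditioned.
#'
#' @param counts numeric length-3: initial counts `(N1, N2, N3)`, all `>= 0`.
#' @param t time (s), scalar or vector, `>= 0`.
#' @param lambda numeric length-3 decay constants (1/s); defaults to the
#'   chain in [radon_nuclides()].
#' @return If `t` is scalar, a named numeric length-3 vector
#'   `(N1, N2, N3)`; otherwise a tibble with columns `t`, `N1`, `N2`, `N3`.
#' @export
#' @examples
#' bateman_evolve(c(1000, 0, 0), 730)
bateman_evolve <- function(counts, t,
                           lambda = radon_nuclides()$decay_constant[1:3]) {
  stopifnot(length(counts) == 3, length(lambda) == 3)
  if (any(counts < 0)) abort("`counts` must be non-negative")
  if (any(t < 0)) abort("`t` must be non-negative")
  M <- lapply(t, function(ti) bateman_matrix(ti, lambda))
  out <- vapply(M, function(m) as.numeric(m %*% counts), numeric(3))
  out <- pmax(out, 0) # guard against -1e-17 round-off
  if (length(t) == 1L) {
    setNames(as.numeric(out), c("N1", "N2", "N3"))
  } else {
    tibble(t = t, N1 = out[1, ], N2 = out[2, ], N3 = out[3, ])
  }
}

#' Bateman transfer matrix
#'
#' Lower-triangular matrix `M(t)` such that `N(t) = M(t) %*% N(0)` for the
#' three-member chain. Column `j` is the fate after time `t` of one nucleus
#' that starts as species `j` (the terminal species is not represented:
#' column sums `< 1` are nuclei that reached Pb-210).
#'
#' @inheritParams bateman_evolve
#' @return 3x3 numeric matrix.
#' @export
bateman_matrix <- function(t, lambda = radon_nuclides()$decay_constant[1:3]) {
  stopifnot(length(lambda) == 3, t >= 0)
  l1 <- lambda[1]; l2 <- lambda[2]; l3 <- lambda[3]
  m <- matrix(0, 3, 3)
  m[1, 1] <- exp(-l1 * t)
  m[2, 1] <- l1 * .ediff1(l1, l2, t)
  m[2, 2] <- exp(-l2 * t)
  m[3, 1] <- l1 * l2 * .ediff2(l1, l2, l3, t)
  m[3, 2] <- l2 * .ediff1(l2, l3, t)
  m[3, 3] <- exp(-l3 * t)
  m
}

#' Bernoulli decay draw over a time step
#'
#' Stochastic counterpart of exponential decay: over a step `dt` a nucleus
#' with decay constant `lambda` decays with probability
#' `p = 1 - exp(-lambda * dt)`. Reproducible under `set.seed()`.
#'
#' @param lambda decay constant (1/s).
#' @param dt time step (s), `> 0`.
#' @param n number of independent draws.
#' @return logical vector of length `n`: `TRUE` = decayed in this step.
#' @export
#' @examples
#' set.seed(1)
#' mean(sample_decay(3.788e-3, 0.1, 1e4))
sample_decay <- function(lambda, dt, n = 1L) {
  if (any(dt <= 0)) abort("`dt` must be positive")
  p <- -expm1(-lambda * dt)
  runif(n) < p
}

#' Sample full per-nucleus chain histories
#'
#' For `n` nuclei all starting as `species`, draws the exponential waiting
#' times of every remaining chain step and returns the cumulative times at
#' which each transition happens. Used by the event-driven dynamic
#' simulation; exact sampling of the same process that the fixed-step
#' Bernoulli scheme discretises.
#'
#' @param species starting species name.
#' @param n number of nuclei.
#' @param nuclides nuclide table.
#' @return tibble with one row per nucleus: columns `t_po218`, `t_pb214`,
#'   `t_bi214` give the cumulative time (s, from the nucleus' own clock
#'   start) at which that species decays; `NA` for stages upstream of the
#'   starting species.
#' @export
sample_chain_history <- function(species, n, nuclides = radon_nuclides()) {
  chain <- c("po218", "pb214", "bi214")
  start <- match(species, chain)
  if (is.na(start)) abort("`species` must be a radioactive chain member")
  lam <- nuclides$decay_constant[match(chain, nuclides$name)]
  out <- matrix(NA_real_, nrow = n, ncol = 3,
                dimnames = list(NULL, paste0("t_", chain)))
  acc <- rep(0, n)
  for (k in start:3) {
    acc <- acc + rexp(n, rate = lam[k])
    out[, k] <- acc
  }
  as_tibble(out)
}
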