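#' Short-lived radon progeny nuclide table
#'
#' The decay chain considered is Po-218 -> Pb-214 -> Bi-214/Po-214 -> Pb-210,
#' with Pb-210 treated as an inert terminal species (its 22 y half-life is
#' effectively infinite on the time scale of bronchial clearance). Bi-214 and
#' Po-214 are merged into a single species carrying Bi-214's half-life: the
#' 164 us half-life of Po-214 makes its alpha emission effectively
#' instantaneous at the Bi-214 decay site, so the merged species emits the
#' 7.69 MeV alpha of Po-214. Po-218 itself emits a 6.0 MeV alpha; the Pb-214
#' and Bi-214 steps are beta transitions and deposit no alpha energy here.
#'
#' Half-lives default to 3.05 min (Po-218), 26.8 min (Pb-214) and 19.7 min
#' (Bi-214); they are configuration values and can be overridden.
#'
#' @param half_lives_s optional named numeric vector overriding the default
#'   half-lives in seconds; names among `"po218"`, `"pb214"`, `"bi214"`.
#' @return A tibble with columns `name`, `half_life_s`, `decay_constant`
#'   (1/s, `log(2)/half_life_s`), `alpha_energy_MeV` (`NA` for pure beta
#'   steps and for the terminal species) and `successor` (`NA` marks the
#'   terminal species).
#' @export
#' @examples
#' radon_nuclides()
radon_nuclides <- function(half_lives_s = NULL) {
  hl <- c(po218 = 3.05 * 60, pb214 = 26.8 * 60, bi214 = 19.7 * 60)
  if (!is.null(half_lives_s)) {
    bad <- setdiff(names(half_lives_s), names(hl))
    if (length(bad) > 0) {
      abort(paste0("unknown nuclide in `half_lives_s`: ", paste(bad, collapse = ", ")))
    }
    hl[names(half_lives_s)] <- half_lives_s
  }
  tibble(
    name = c("po218", "pb214", "bi214", "pb210"),
    half_life_s = c(unname(hl), Inf),
    decay_constant = c(decay_constant_of(unname(hl)), 0),
    alpha_energy_MeV = c(6.0, NA_real_, 7.69, NA_real_),
    successor = c("pb214", "bi214", "pb210", NA_character_)
  )
}

#' Decay constant from half-life
#'
#' @param half_life half-life (s); must be positive (may be `Inf`).
#' @return decay constant `log(2) / half_life` (1/s).
#' @export
#' @examples
#' decay_constant_of(183) # Po-218
decay_constant_of <- function(half_life) {
  if (any(!is.finite(half_life) & !is.infinite(half_life)) || any(half_life <= 0)) {
    abort("`half_life` must be positive")
  }
  log(2) / half_life
}

#' Chain successor of a nuclide
#'
#' Maps each species to the next member of the chain. The terminal species
#' Pb-210 maps to `NA`, signalling removal from radioactive tracking.
#'
#' @param species character vector of nuclide names.
#' @param nuclides nuclide table, see [radon_nuclides()].
#' @return character vector of successors (`NA` = terminal).
#' @export
#' @examples
#' transmute_nuclide("po218")
transmute_nuclide <- function(species, nuclides = radon_nuclides()) {
  idx <- match(species, nuclides$name)
  if (anyNA(idx)) {
    abort(paste0("unknown species: ", paste(unique(species[is.na(idx)]), collapse = ", ")))
  }
  nuclides$successor[idx]
}

#' Read / write the nuclide table
#'
#' Plain-CSV round trip of the nuclide configuration
#' (`name, half_life_s, alpha_energy_MeV, successor`).
#'
#' @param path file path.
#' @param nuclides nuclide table to write.
#' @return `read_nuclide_table()` returns the table with the decay constant
#'   recomputed from the half-life; `write_nuclide_table()` returns `path`
#'   invisibly.
#' @export
read_nuclide_table <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  tb |>
    mutate(decay_constant = ifelse(is.finite(.data$half_life_s),
      log(2) / .data$half_life_s, 0
    )) |>
    select("name", "half_life_s", "decay_constant", "alpha_energy_MeV", "successor")
}

#' @rdname read_nuclide_table
#' @export
write_nuclide_table <- function(nuclides, path) {
  readr::write_csv(select(nuclides, -"decay_constant"), path)
  invisible(path)
}
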