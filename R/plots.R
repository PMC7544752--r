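# ggplot2 views of the main result types.

#' Plot per-generation deposition fractions
#'
#' Bar panel per nuclide of the airway-generation deposition fractions
#' (inhalation + exhalation stacked), with the extrathoracic fraction at
#' generation 0.
#'
#' @param object `wholelung_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.wholelung_result <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(
    tb,
    ggplot2::aes(x = .data$generation, y = .data$fraction, fill = .data$phase)
  ) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$nuclide)) +
    ggplot2::labs(
      x = "airway generation (0 = extrathoracic)",
      y = "deposition fraction of inhaled activity", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot the activity build-up in the bifurcation
#'
#' Per-species nuclide counts and total activity against exposure time,
#' with the detected quasi-steady time marked.
#'
#' @param object `bifsim_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.bifsim_result <- function(object, ...) {
  tb <- tidy(object)
  p <- ggplot2::ggplot(
    tb, ggplot2::aes(.data$time_min, .data$value, colour = .data$series)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (min)", y = "nuclei in residence / activity (Bq)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  if (is.finite(object$quasi_steady_min %||% NA)) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$quasi_steady_min, linetype = "dashed"
    )
  }
  p
}

#' Plot an enhancement-factor map
#'
#' Unrolled (axial x azimuth) tile map of the patch enhancement factors,
#' one facet per branch.
#'
#' @param ef tessellation with `ef` column, from [enhancement_map()].
#' @return a ggplot.
#' @export
plot_enhancement_map <- function(ef) {
  ggplot2::ggplot(ef, ggplot2::aes(
    xmin = .data$ax0_mm, xmax = .data$ax1_mm,
    ymin = .data$az0_deg, ymax = .data$az1_deg, fill = .data$ef
  )) +
    ggplot2::geom_rect() +
    ggplot2::facet_wrap(ggplot2::vars(.data$branch), scales = "free_x") +
    ggplot2::scale_fill_viridis_c(trans = "log1p") +
    ggplot2::labs(x = "axial (mm)", y = "azimuth (deg)", fill = "EF") +
    ggplot2::theme_minimal()
}

#' Plot residence-time distribution of a trajectory set
#'
#' @param trajectories `trajectory_set`.
#' @param bins histogram bins.
#' @return a ggplot.
#' @export
plot_residence_times <- function(trajectories, bins = 40) {
  ggplot2::ggplot(
    trajectories$info, ggplot2::aes(.data$residence_min)
  ) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::labs(x = "residence time (min)", y = "trajectories") +
    ggplot2::theme_minimal()
}

#' Plot the dose-response curves
#'
#' Death and transformation probability against nucleus dose for the
#' configured parameters.
#'
#' @param params `response_parameters`.
#' @param d_max upper dose (Gy).
#' @return a ggplot.
#' @export
plot_dose_response <- function(params = response_parameters(), d_max = 4) {
  d <- seq(0, d_max, length.out = 200)
  tb <- bind_rows(
    tibble(dose_Gy = d, p = cell_death_probability(d, params), endpoint = "death"),
    tibble(
      dose_Gy = d, p = cell_transformation_probability(d, params),
      endpoint = "transformation"
    )
  )
  ggplot2::ggplot(tb, ggplot2::aes(.data$dose_Gy, .data$p)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$endpoint), scales = "free_y") +
    ggplot2::labs(x = "nucleus dose (Gy)", y = "probability") +
    ggplot2::theme_minimal()
}
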