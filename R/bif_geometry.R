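# Parametric wall-surface model of the target airway bifurcation: per-branch
# cylindrical charts (branch, axial, azimuth), the stitching rule between
# daughter and parent charts, the distance-to-carina metric and the
# 100 um x 100 um patch tessellation.
#
# Chart conventions:
#   * daughter_a / daughter_b: axial = 0 at the daughter inlet (the distal
#     end fed from generation 6), increasing towards the bifurcation;
#     azimuth 180 deg faces the sibling daughter (carinal side).
#   * parent: axial = 0 at the bifurcation, increasing towards the parent
#     outlet; the carinal ridge maps to azimuths 90 (daughter A side) and
#     270 (daughter B side).
#   * Each daughter's circumference maps onto half of the parent
#     circumference: az_p = 90 + (az_d - 180)/2 for daughter A and
#     az_p = (270 + (az_d - 180)/2) mod 360 for daughter B.

#' Geometry of the target airway bifurcation
#'
#' Morphometry of the modelled generation 4/5 bifurcation (a segmental
#' bronchus and its two sub-segmental daughters): parent 0.72 cm long x
#' 0.56 cm diameter, daughters 1.20 cm x 0.45 cm, bifurcation angle 35 deg,
#' daughter curvature radius 1.43 cm, carinal curvature radius 0.1 cm.
#'
#' @param parent_length_cm,daughter_length_cm,parent_diameter_cm,daughter_diameter_cm,bifurcation_angle_deg,daughter_curvature_radius_cm,carinal_radius_cm
#'   geometric parameters (defaults above).
#' @return named list of class `bifurcation_geometry`.
#' @export
bifurcation_geometry <- function(parent_length_cm = 0.72,
                                 daughter_length_cm = 1.20,
                                 parent_diameter_cm = 0.56,
                                 daughter_diameter_cm = 0.45,
                                 bifurcation_angle_deg = 35.0,
                                 daughter_curvature_radius_cm = 1.43,
                                 carinal_radius_cm = 0.1) {
  vals <- c(
    parent_length_cm, daughter_length_cm, parent_diameter_cm,
    daughter_diameter_cm, bifurcation_angle_deg,
    daughter_curvature_radius_cm, carinal_radius_cm
  )
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all geometry parameters must be positive")
  }
  if (daughter_diameter_cm >= parent_diameter_cm) {
    abort("daughter diameter must be smaller than parent diameter")
  }
  structure(
    list(
      parent_length_cm = parent_length_cm,
      daughter_length_cm = daughter_length_cm,
      parent_diameter_cm = parent_diameter_cm,
      daughter_diameter_cm = daughter_diameter_cm,
      bifurcation_angle_deg = bifurcation_angle_deg,
      daughter_curvature_radius_cm = daughter_curvature_radius_cm,
      carinal_radius_cm = carinal_radius_cm
    ),
    class = "bifurcation_geometry"
  )
}

# smallest angular difference in degrees, in [0, 180]
.ang_diff <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

# branch lengths / radii in mm
.branch_length_mm <- function(branch, geometry) {
  ifelse(branch == "parent", geometry$parent_length_cm * 10,
    geometry$daughter_length_cm * 10
  )
}
.branch_radius_mm <- function(branch, geometry) {
  ifelse(branch == "parent", geometry$parent_diameter_cm * 5,
    geometry$daughter_diameter_cm * 5
  )
}

#' Map a daughter azimuth to the parent chart
#'
#' Stitching rule at the bifurcation: each daughter's full circumference
#' maps onto its half of the parent circumference, with the carinal side
#' (daughter azimuth 180) landing on the parent ridge azimuth (90 for
#' daughter A, 270 for daughter B).
#'
#' @param branch `"daughter_a"` or `"daughter_b"` (vectorised).
#' @param azimuth_deg daughter azimuth (degrees).
#' @return parent azimuth (degrees in \[0, 360)).
#' @export
stitch_azimuth <- function(branch, azimuth_deg) {
  ridge <- ifelse(branch == "daughter_a", 90, 270)
  (ridge + (azimuth_deg - 180) / 2) %% 360
}

#' Surface distance to the carinal ridge apex
#'
#' Euclidean distance in the unrolled per-branch chart between a wall point
#' and the carinal ridge (the dividing spur at the bifurcation), in mm.
#' Used by the slow-clearance-zone profile and by the hot-spot definitions.
#'
#' @param branch,axial_mm,azimuth_deg surface coordinates (vectorised).
#' @param geometry bifurcation geometry.
#' @return distance (mm).
#' @export
carina_distance_mm <- function(branch, axial_mm, azimuth_deg,
                               geometry = bifurcation_geometry()) {
  rad <- pi / 180
  L_d <- geometry$daughter_length_cm * 10
  r_d <- .branch_radius_mm("daughter_a", geometry)
  r_p <- .branch_radius_mm("parent", geometry)
  is_par <- branch == "parent"
  arc <- ifelse(is_par,
    r_p * pmin(.ang_diff(azimuth_deg, 90), .ang_diff(azimuth_deg, 270)) * rad,
    r_d * .ang_diff(azimuth_deg, 180) * rad
  )
  ax <- ifelse(is_par, axial_mm, L_d - axial_mm)
  sqrt(ax^2 + arc^2)
}

#' Tessellate the bifurcation wall into square patches
#'
#' Covers the lateral surface of the parent and the two daughter branches
#' with patches of nominally `patch_mm` x `patch_mm` (default 100 um x
#' 100 um, area 1e-8 m^2); the per-branch patch counts are rounded so the
#' tessellation is exact, keeping individual areas within a few percent of
#' nominal. End caps and the carinal saddle are not meshed separately: the
#' branch cylinders meet at the bifurcation plane.
#'
#' @param geometry bifurcation geometry.
#' @param patch_mm nominal patch edge (mm).
#' @return tibble of class `bifurcation_surface` with columns `patch_id`,
#'   `branch`, `ax0_mm`, `ax1_mm`, `az0_deg`, `az1_deg`, `area_mm2`,
#'   `carina_mm` (distance of the patch centre to the carinal apex).
#' @export
build_surface <- function(geometry = bifurcation_geometry(), patch_mm = 0.1) {
  circum <- function(r) 2 * pi * r
  per_branch <- function(branch) {
    L <- .branch_length_mm(branch, geometry)
    r <- .branch_radius_mm(branch, geometry)
    if (patch_mm >= circum(r)) abort("patch larger than branch circumference")
    n_ax <- max(1L, round(L / patch_mm))
    n_az <- max(1L, round(circum(r) / patch_mm))
    h <- L / n_ax
    daz <- 360 / n_az
    grid <- tidyr::expand_grid(i = seq_len(n_ax), j = seq_len(n_az))
    tibble(
      branch = branch,
      ax0_mm = (grid$i - 1) * h, ax1_mm = grid$i * h,
      az0_deg = (grid$j - 1) * daz, az1_deg = grid$j * daz,
      area_mm2 = h * circum(r) / n_az
    )
  }
  tb <- bind_rows(
    per_branch("parent"), per_branch("daughter_a"), per_branch("daughter_b")
  )
  tb$patch_id <- seq_len(nrow(tb))
  tb$carina_mm <- carina_distance_mm(
    tb$branch, (tb$ax0_mm + tb$ax1_mm) / 2, (tb$az0_deg + tb$az1_deg) / 2,
    geometry
  )
  class(tb) <- c("bifurcation_surface", class(tb))
  attr(tb, "geometry") <- geometry
  attr(tb, "patch_mm") <- patch_mm
  tb
}

#' Analytic lateral surface areas of the bifurcation
#'
#' @param geometry bifurcation geometry.
#' @return named numeric (mm^2): parent, daughters, total.
#' @export
surface_areas_mm2 <- function(geometry = bifurcation_geometry()) {
  par <- pi * geometry$parent_diameter_cm * 10 * geometry$parent_length_cm * 10
  dau <- 2 * pi * geometry$daughter_diameter_cm * 10 * geometry$daughter_length_cm * 10
  c(parent = par, daughters = dau, total = par + dau)
}

#' Local chart around the carinal apex
#'
#' Maps surface coordinates near the carinal ridge to the unrolled local
#' frame used by the hot-spot kernel and the hot-spot dosimetry tile:
#' `u_mm` is the signed along-path offset (negative on the daughter side
#' of the ridge, positive on the parent side) and `w_mm` the transverse
#' arc offset along the ridge. Cross-branch continuity is approximate
#' (each branch is unrolled separately), which is adequate within a
#' millimetre of the apex.
#'
#' @param branch,axial_mm,azimuth_deg surface coordinates (vectorised).
#' @param geometry bifurcation geometry.
#' @return tibble `u_mm`, `w_mm`, `r_mm` (= `sqrt(u^2 + w^2)`).
#' @export
carina_chart_coords <- function(branch, axial_mm, azimuth_deg,
                                geometry = bifurcation_geometry()) {
  rad <- pi / 180
  L_d <- geometry$daughter_length_cm * 10
  r_d <- .branch_radius_mm("daughter_a", geometry)
  r_p <- .branch_radius_mm("parent", geometry)
  is_par <- branch == "parent"
  u <- ifelse(is_par, axial_mm, -(L_d - axial_mm))
  signed_arc <- function(az, center, r) {
    d <- ((az - center + 180) %% 360) - 180
    d * rad * r
  }
  w_d <- signed_arc(azimuth_deg, 180, r_d)
  d90 <- abs(((azimuth_deg - 90 + 180) %% 360) - 180)
  d270 <- abs(((azimuth_deg - 270 + 180) %% 360) - 180)
  w_p <- ifelse(d90 <= d270,
    signed_arc(azimuth_deg, 90, r_p),
    signed_arc(azimuth_deg, 270, r_p)
  )
  w <- ifelse(is_par, w_p, w_d)
  tibble(u_mm = u, w_mm = w, r_mm = sqrt(u^2 + w^2))
}

# map surface coordinates to patch ids of a tessellation; coordinates on a
# shared border go to the higher-index patch edge consistently via floor()
.locate_patch <- function(surface, branch, axial_mm, azimuth_deg) {
  geometry <- attr(surface, "geometry")
  out <- integer(length(branch))
  for (br in unique(branch)) {
    sel <- branch == br
    sub <- surface[surface$branch == br, ]
    L <- .branch_length_mm(br, geometry)
    n_ax <- length(unique(sub$ax0_mm))
    n_az <- length(unique(sub$az0_deg))
    i <- pmin(pmax(floor(axial_mm[sel] / (L / n_ax)), 0), n_ax - 1)
    j <- pmin(pmax(floor((azimuth_deg[sel] %% 360) / (360 / n_az)), 0), n_az - 1)
    # rows of `sub` are ordered by (i, j)
    out[sel] <- sub$patch_id[i * n_az + j + 1]
  }
  out
}
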