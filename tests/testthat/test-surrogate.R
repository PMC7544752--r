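geo <- bifurcation_geometry()

test_that("geometry carries the configured morphometry and validates input", {
  expect_equal(geo$parent_length_cm, 0.72)
  expect_equal(geo$daughter_length_cm, 1.20)
  expect_equal(geo$parent_diameter_cm, 0.56)
  expect_equal(geo$daughter_diameter_cm, 0.45)
  expect_equal(geo$bifurcation_angle_deg, 35)
  expect_equal(geo$carinal_radius_cm, 0.1)
  expect_error(bifurcation_geometry(parent_length_cm = -1), "positive")
  expect_error(bifurcation_geometry(daughter_diameter_cm = 0.6), "smaller")
})

test_that("azimuth stitching maps daughters onto their parent half", {
  # carinal side of each daughter lands on its parent ridge azimuth
  expect_equal(stitch_azimuth("daughter_a", 180), 90)
  expect_equal(stitch_azimuth("daughter_b", 180), 270)
  # full daughter circumference -> half parent circumference
  expect_equal(stitch_azimuth("daughter_a", 0), 0)
  expect_equal(stitch_azimuth("daughter_a", 360), 180)
  expect_equal(stitch_azimuth("daughter_b", 0), 180)
  # continuity and injectivity on a grid
  az <- seq(0, 359, by = 1)
  pa <- stitch_azimuth(rep("daughter_a", length(az)), az)
  expect_true(all(pa >= 0 & pa < 360))
  expect_equal(length(unique(round(pa, 9))), length(az))
})

test_that("carina distance is zero at the apex and grows outward", {
  L_d <- geo$daughter_length_cm * 10
  expect_equal(carina_distance_mm("daughter_a", L_d, 180), 0)
  expect_equal(carina_distance_mm("parent", 0, 90), 0)
  expect_equal(carina_distance_mm("parent", 0, 270), 0)
  # pure axial offsets
  expect_equal(carina_distance_mm("parent", 3, 90), 3)
  expect_equal(carina_distance_mm("daughter_a", L_d - 4, 180), 4)
  # pure transverse offsets follow the arc length
  r_d <- geo$daughter_diameter_cm * 5
  expect_equal(carina_distance_mm("daughter_a", L_d, 170),
    r_d * 10 * pi / 180)
})

test_that("tessellation covers the analytic area with ~100 um patches", {
  surf <- build_surface(geo)
  areas <- surface_areas_mm2(geo)
  expect_equal(sum(surf$area_mm2), unname(areas["total"]), tolerance = 1e-9)
  expect_equal(
    sum(surf$area_mm2[surf$branch == "parent"]),
    unname(areas["parent"]), tolerance = 1e-9
  )
  # patch edges stay within a few percent of nominal
  h <- surf$ax1_mm - surf$ax0_mm
  expect_true(all(abs(h - 0.1) < 0.01))
  expect_true(all(abs(surf$area_mm2 - 0.01) < 0.001))
  expect_equal(surf$patch_id, seq_len(nrow(surf)))
  # total patch count ~ area / 0.01 mm^2
  expect_equal(nrow(surf), round(unname(areas["total"]) / 0.01),
    tolerance = 0.01)
})

test_that("patch lookup returns the containing patch", {
  surf <- build_surface(geo, patch_mm = 1)
  mid_ax <- (surf$ax0_mm + surf$ax1_mm) / 2
  mid_az <- (surf$az0_deg + surf$az1_deg) / 2
  got <- radonclear:::.locate_patch(surf, surf$branch, mid_ax, mid_az)
  expect_equal(got, surf$patch_id)
})

test_that("enhancement map has area-weighted mean exactly 1", {
  set.seed(5)
  surf <- build_surface(geo, patch_mm = 0.5)
  pts <- sample_deposition_site(5000, deposition_pattern("inhalation"), geo)
  pts$weight <- runif(5000, 0.5, 1.5)
  ef <- enhancement_map(pts, surf)
  expect_equal(sum(ef$ef * ef$area_mm2) / sum(ef$area_mm2), 1,
    tolerance = 1e-6)
  expect_equal(sum(ef$count), sum(pts$weight), tolerance = 1e-9)
  expect_error(enhancement_map(pts[0, ], surf), "at least one")
})

test_that("deposition sampler matches its analytic patch density (chi^2)", {
  set.seed(9)
  surf <- build_surface(geo, patch_mm = 2)
  pat <- deposition_pattern("inhalation")
  p <- deposition_site_density(surf, pat)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  n <- 40000
  pts <- sample_deposition_site(n, pat, geo)
  idx <- radonclear:::.locate_patch(surf, pts$branch, pts$axial_mm,
    pts$azimuth_deg)
  obs <- tabulate(idx, nbins = nrow(surf))
  # pool patches with small expectation into one bin (if any)
  big <- p * n >= 5
  o <- obs[big]
  e <- p[big] * n
  if (any(!big)) {
    o <- c(o, sum(obs[!big]))
    e <- c(e, sum(p[!big]) * n)
  }
  chi2 <- sum((o - e)^2 / e)
  dof <- length(o) - 1
  expect_gt(stats::pchisq(chi2, dof, lower.tail = FALSE), 1e-3)
})

test_that("exhalation pattern is nearly uniform, inhalation carinal", {
  surf <- build_surface(geo, patch_mm = 1)
  p_in <- deposition_site_density(surf, deposition_pattern("inhalation"))
  p_ex <- deposition_site_density(surf, deposition_pattern("exhalation"))
  apex <- which.min(surf$carina_mm)
  expect_gt(p_in[apex] / (surf$area_mm2[apex] / sum(surf$area_mm2)), 50)
  expect_lt(max(p_ex / (surf$area_mm2 / sum(surf$area_mm2))), 20)
})

test_that("mucus field conserves gel volume flux at the merge", {
  f <- mucus_field(geo)
  # v_p * d_p = 2 * v_d * d_d (constant film thickness)
  expect_equal(
    f$parent_velocity_mm_min * geo$parent_diameter_cm,
    2 * f$inlet_velocity_mm_min * geo$daughter_diameter_cm,
    tolerance = 1e-12
  )
  # within 1% from sampled speeds at matched carina distance (the slow-zone
  # factor cancels): parent outlet at az 180 and the daughter point at the
  # same 8.44 mm distance
  d_ref <- carina_distance_mm("parent", geo$parent_length_cm * 10, 180, geo)
  ax_d <- geo$daughter_length_cm * 10 - d_ref
  v_d <- mucus_velocity_at("daughter_a", ax_d, 180, f)$speed_mm_min
  v_p <- mucus_velocity_at("parent", geo$parent_length_cm * 10, 180, f)$speed_mm_min
  expect_equal(v_p * geo$parent_diameter_cm, 2 * v_d * geo$daughter_diameter_cm,
    tolerance = 0.01)
  expect_error(mucus_velocity_at("parent", 100, 0, f), "off the")
})

test_that("slow zone reduces speed most at the carinal apex", {
  f <- mucus_field(geo)
  v_apex <- mucus_velocity_at("daughter_a", geo$daughter_length_cm * 10, 180, f)
  v_far <- mucus_velocity_at("daughter_a", 0, 0, f)
  expect_lt(v_apex$speed_mm_min, 0.05 * v_far$speed_mm_min)
  expect_gt(v_apex$speed_mm_min, 0)
})

test_that("trajectories integrate to the calibrated residence statistics", {
  tr <- clearance_trajectories(2000)
  rs <- residence_summary(tr)
  expect_equal(rs$n, 2000)
  expect_equal(rs$mean_min, 20, tolerance = 0.1)
  expect_gt(rs$max_min, 25)
  expect_true(all(tr$info$residence_min > 0))
  # cumulative times are monotone along both charts
  expect_true(all(diff(tr$ct_d[, 1]) > 0))
  expect_true(all(diff(tr$ct_p[, 1]) > 0))
  # parent clock continues the daughter clock
  expect_true(all(tr$ct_p[1, ] >= tr$ct_d[nrow(tr$ct_d), ] - 1e-9))
})

test_that("trajectory step-halving changes residence times < 0.5%", {
  f <- mucus_field(geo)
  t1 <- clearance_trajectories(40, f, step_mm = 0.02)
  t2 <- clearance_trajectories(40, f, step_mm = 0.01)
  rel <- abs(t1$info$residence_min - t2$info$residence_min) /
    t2$info$residence_min
  expect_lt(max(rel), 0.005)
})

test_that("trace_trajectory agrees with the pre-computed set", {
  f <- mucus_field(geo)
  tr <- clearance_trajectories(200, f)
  one <- trace_trajectory("daughter_a", 0, tr$info$azimuth_daughter_deg[5], f)
  expect_s3_class(one, "clearance_trajectory")
  expect_equal(one$time_min[nrow(one)], tr$info$residence_min[5],
    tolerance = 1e-6)
  expect_equal(one$branch[nrow(one)], "parent")
  expect_error(trace_trajectory("parent", 100, 0, f), "off the surface")
})

test_that("nearest trajectory matches a brute-force search", {
  tr <- clearance_trajectories(50)
  set.seed(3)
  br <- sample(c("daughter_a", "daughter_b", "parent"), 100, replace = TRUE)
  ax <- runif(100, 0, 5)
  az <- runif(100, 0, 360)
  got <- nearest_trajectory(tr, br, ax, az)
  brute <- vapply(seq_along(br), function(i) {
    info <- tr$info
    if (br[i] == "parent") {
      d <- radonclear:::.ang_diff(info$azimuth_parent_deg, az[i])
      cand <- info$id
    } else {
      sub <- info[info$branch == br[i], ]
      d <- radonclear:::.ang_diff(sub$azimuth_daughter_deg, az[i])
      cand <- sub$id
    }
    cand[which.min(d)] # which.min takes the first (lowest id) on ties
  }, integer(1))
  expect_equal(got, brute)
})

test_that("time-remaining and position-after are mutually consistent", {
  tr <- clearance_trajectories(100)
  ids <- nearest_trajectory(tr, c("daughter_a", "parent"), c(2, 1), c(10, 100))
  rem <- trajectory_time_remaining(tr, ids, c("daughter_a", "parent"), c(2, 1))
  expect_true(all(rem > 0))
  # advancing by the full remaining time reaches the parent outlet
  pos <- trajectory_position_after(tr, ids, c("daughter_a", "parent"),
    c(2, 1), rem)
  expect_equal(pos$branch, c("parent", "parent"))
  expect_equal(pos$axial_mm, rep(geo$parent_length_cm * 10, 2),
    tolerance = 1e-6)
  # advancing by zero stays in place
  pos0 <- trajectory_position_after(tr, ids[1], "daughter_a", 2, 0)
  expect_equal(pos0$branch, "daughter_a")
  expect_equal(pos0$axial_mm, 2, tolerance = 1e-6)
})
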