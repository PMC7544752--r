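test_that("sim_config validates its arguments", {
  cfg <- sim_config(3, 16)
  expect_s3_class(cfg, "sim_config")
  expect_error(sim_config(4, 1), "scenario")
  expect_error(sim_config(1, -1))
  expect_error(sim_config(1, 1, replication = 0))
})

test_that("bifurcation sources are positive per-species rates", {
  wl <- simulate_whole_lung()
  src <- bifurcation_sources(wl)
  expect_s3_class(src, "bif_sources")
  expect_equal(nrow(src$deposition), 6) # 3 nuclides x 2 phases
  expect_true(all(src$deposition$rate_per_s > 0))
  # inhalation deposits dominate exhalation deposits
  r <- tapply(src$deposition$rate_per_s, src$deposition$phase, sum)
  expect_gt(r[["inhalation"]], 5 * r[["exhalation"]])
  expect_true(all(src$entry$rate_per_s >= 0))
})

test_that("phase-gated event times land in the correct half-cycles", {
  set.seed(2)
  t_in <- radonclear:::.sample_phase_times(5000, 600, 5, "inhalation")
  t_ex <- radonclear:::.sample_phase_times(5000, 600, 5, "exhalation")
  expect_true(all(t_in %% 5 < 2.5))
  expect_true(all(t_ex %% 5 >= 2.5))
  expect_true(all(t_in >= 0 & t_in < 600))
  # uniform over the union of windows
  expect_gt(stats::ks.test((t_in %% 5) / 2.5, "punif")$p.value, 1e-3)
})

test_that("event-driven engine conserves nuclei exactly", {
  set.seed(21)
  src <- synthetic_sources(0.05)
  tr <- clearance_trajectories(200)
  sim <- run_bifurcation_sim(sim_config(3, 1, replication = 3), src, tr)
  bk <- sim$bookkeeping
  expect_equal(bk$deposited + bk$entered, bk$exited + bk$in_residence,
    tolerance = 1e-12)
  # every particle appears at most once per chain stage in the event log
  expect_true(all(table(sim$events$particle, sim$events$species) <= 1))
  expect_true(all(sim$events$weight == 1 / 3))
  expect_true(all(sim$events$time_s <= 3600))
})

test_that("event-driven and fixed-step engines agree with the analytic rates", {
  set.seed(22)
  src <- synthetic_sources(0.5)
  cfg <- sim_config(2, 1 / 6, replication = 1, timestep_s = 0.1)
  T_s <- 600
  sim <- run_bifurcation_sim(cfg, src)
  st <- new_step_state()
  while (st$time_s < T_s - 1e-9) {
    st <- step_bifurcation_sim(st, cfg, src)
  }
  # expected deposits: 6 sources x rate x half the exposure (phase gating)
  expected <- 6 * 0.5 * T_s / 2
  sd_exp <- sqrt(expected)
  expect_lt(abs(sim$bookkeeping$deposited - expected), 5 * sd_exp)
  expect_lt(abs(st$counters$deposited - expected), 5 * sd_exp)
  # alpha decays within the window agree between the engines (Poisson bands)
  a_ev <- sum(!is.na(sim$events$alpha_energy_MeV))
  a_st <- sum(!is.na(st$events$alpha_energy_MeV))
  expect_lt(abs(a_ev - a_st), 5 * sqrt((a_ev + a_st) / 2 + 1) * sqrt(2))
  # scenario 2: no motion, no entries
  expect_equal(sim$bookkeeping$entered, 0)
  expect_equal(sim$bookkeeping$exited, 0)
})

test_that("scenario 1 forces the uniform pattern", {
  set.seed(23)
  src <- synthetic_sources(0.5)
  sim <- run_bifurcation_sim(sim_config(1, 0.5, replication = 1), src)
  # no deposit should concentrate at the apex beyond the uniform share
  d <- carina_distance_mm(sim$particles$branch, sim$particles$axial_mm,
    sim$particles$azimuth_deg)
  frac_near <- mean(d < 1)
  area_near <- pi * 1^2 * 2 / sum(surface_areas_mm2()["total"]) # two sides
  expect_lt(frac_near, area_near * 5 + 0.01)
})

test_that("clearance empties the bifurcation: scenario 3 retains fewer nuclei", {
  set.seed(24)
  src <- synthetic_sources(0.2)
  tr <- clearance_trajectories(200)
  sim2 <- run_bifurcation_sim(sim_config(2, 2, replication = 1, seed = 7), src)
  sim3 <- run_bifurcation_sim(sim_config(3, 2, replication = 1, seed = 7),
    src, tr)
  expect_equal(sim3$bookkeeping$in_residence + sim3$bookkeeping$exited,
    sim3$bookkeeping$deposited + sim3$bookkeeping$entered)
  expect_gt(sim3$bookkeeping$exited, 0)
  # fewer alpha decays happen inside the bifurcation when clearance is on
  expect_lt(sim3$bookkeeping$alpha_decays / (sim3$bookkeeping$deposited +
    sim3$bookkeeping$entered),
  sim2$bookkeeping$alpha_decays / sim2$bookkeeping$deposited)
})

test_that("activity time series counts species presence", {
  set.seed(25)
  src <- synthetic_sources(0.5)
  sim <- run_bifurcation_sim(sim_config(2, 0.5, replication = 1), src)
  a <- sim$activity
  expect_equal(a$time_min, 1:30)
  expect_true(all(a$po218 >= 0))
  expect_equal(a$activity_Bq,
    as.numeric(as.matrix(a[, c("po218", "pb214", "bi214")]) %*%
      (log(2) / c(183, 1608, 1182))))
  # tidy/glance/print interfaces
  expect_s3_class(tidy(sim), "tbl_df")
  expect_true("quasi_steady_min" %in% names(glance(sim)))
  expect_output(print(sim), "bifsim_result")
})

test_that("quasi-steady detector finds the plateau of a known series", {
  # synthetic saturation curve a(t) = 1 - exp(-t/10): within 5% of the
  # asymptote from t ~ 30 min on
  t <- 1:600
  act <- tibble::tibble(time_min = t, activity_Bq = 1 - exp(-t / 10))
  qs <- radonclear:::.quasi_steady_minute(act)
  expect_true(qs >= 25 && qs <= 35)
  # too-short series gives NA
  expect_true(is.na(radonclear:::.quasi_steady_minute(act[1:60, ])))
})
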