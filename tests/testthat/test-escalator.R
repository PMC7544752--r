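test_that("escalator table reproduces the full-length transit convention", {
  tb <- escalator_table()
  expect_equal(tb$generation, 6:16)
  expect_equal(tb$length_mm[1:2], c(9.0, 7.6))
  expect_equal(tb$velocity_mm_min[1:2], c(0.74, 0.50))
  # cumulative = sum of L/v over generations 6..g
  manual <- cumsum(tb$length_mm / tb$velocity_mm_min * 60)
  expect_equal(tb$clearance_time_exact_s, manual)
  expect_equal(tb$clearance_time_s, round(manual))
  expect_true(all(diff(tb$clearance_time_exact_s) > 0))
  # half-length-start option removes half of the own-generation transit
  th <- escalator_table(half_length_start = TRUE)
  expect_equal(th$clearance_time_exact_s,
    manual - tb$length_mm / tb$velocity_mm_min * 60 / 2)
})

test_that("cumulative clearance times match the published table", {
  # generations 6 and 7 are exact; >= 8 within +/- 2 s (the published
  # table was built from unrounded inputs)
  published <- c(730, 1642, 2806, 4279, 6119, 8459, 11288, 14528,
    19128, 25128, 35028)
  got <- cumulative_clearance_time(6:16)
  expect_equal(got[1:2], published[1:2])
  expect_true(all(abs(got - published) <= 2))
  expect_equal(cumulative_clearance_time(5), 0)
  expect_error(cumulative_clearance_time(4), "escalator range")
  expect_error(cumulative_clearance_time(17), "escalator range")
})

test_that("up-cleared fractions evolve the chain over the transit", {
  up <- upcleared_fractions(6, c(1000, 0, 0))
  expect_equal(up$nuclide, c("po218", "pb214", "bi214"))
  # Po-218 survival over the reported generation-6 clearance time (730 s,
  # the table's rounded convention): e^{-lambda t}
  expect_equal(up$fraction[1], exp(-log(2) / 183 * 730), tolerance = 1e-12)
  expect_equal(up$fraction[1], 0.0630, tolerance = 0.002)
  # the unrounded transit is available on request
  upx <- upcleared_fractions(6, c(1000, 0, 0), exact = TRUE)
  expect_equal(upx$fraction[1], exp(-log(2) / 183 * 9.0 / 0.74 * 60),
    tolerance = 1e-12)
  # nothing deposited -> NA fraction but in-grown arrivals
  expect_true(all(is.na(up$fraction[2:3])))
  expect_true(all(up$arrived[2:3] > 0))
  # Bi-214 in-growth above 100% for the 2:1 Pb:Bi deposit at 730 s
  up2 <- upcleared_fractions(6, c(0, 2000, 1000))
  expect_gt(up2$fraction[3], 1)
  expect_equal(up2$fraction[3], 1.086, tolerance = 0.001)
  # and below 100% for long transits
  up3 <- upcleared_fractions(12, c(0, 2000, 1000))
  expect_lt(up3$fraction[3], 1)
})

test_that("neglect threshold zeroes sub-0.01% survivals", {
  # Po-218 from generation 8 (2806 s, ~ 15 half-lives) is negligible
  up <- upcleared_fractions(8, c(1000, 0, 0))
  expect_equal(up$fraction[1], 0)
  expect_equal(up$arrived[1], 0)
  # just above threshold survives: generation 7 keeps ~0.2%
  up7 <- upcleared_fractions(7, c(1000, 0, 0))
  expect_gt(up7$fraction[1], 1e-4)
})

test_that("entry flux aggregates Bateman-transferred sources over 1/8 subtree", {
  wl <- simulate_whole_lung()
  ef <- build_entry_flux(wl)
  expect_s3_class(ef$flux, "tbl_df")
  expect_equal(sort(ef$flux$nuclide), sort(c("po218", "pb214", "bi214")))
  expect_true(all(ef$flux$rate_per_s >= 0))
  # flux equals the per-source sum
  agg <- tapply(ef$by_source$rate_per_s, ef$by_source$nuclide, sum)
  expect_equal(as.numeric(agg[ef$flux$nuclide]), ef$flux$rate_per_s)
  # Po-218 arrives only from generation 6 (neglect threshold upstream)
  po <- ef$by_source[ef$by_source$nuclide == "po218", ]
  expect_true(all(po$rate_per_s[po$source_generation >= 8] == 0))
  expect_gt(po$rate_per_s[po$source_generation == 6], 0)
  # ramp times are the cumulative clearance times
  expect_equal(unique(ef$by_source$ramp_time_s),
    cumulative_clearance_time(6:16, exact = TRUE))
  # one manual spot check of the subtree/Bateman accounting (generation 6)
  br <- wl$exposure$breathing
  mv <- br$tidal_L * br$frequency_per_min / 1000 / 60
  conc <- wl$exposure$number_concentration_m3
  dep6 <- wl$generations |>
    dplyr::filter(generation == 6) |>
    dplyr::group_by(nuclide) |>
    dplyr::summarise(f = sum(fraction))
  dvec <- setNames(dep6$f, dep6$nuclide)[c("po218", "pb214", "bi214")] *
    conc[c("po218", "pb214", "bi214")] * mv
  M <- bateman_matrix(cumulative_clearance_time(6, exact = TRUE))
  want <- as.numeric(M %*% dvec) / 8
  got6 <- ef$by_source[ef$by_source$source_generation == 6, ]
  expect_equal(got6$rate_per_s, want, tolerance = 1e-12)
})
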