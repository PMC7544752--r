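tab <- stopping_power_table()

test_that("stopping-power table reproduces the anchor CSDA ranges", {
  # off-grid energies are interpolated, hence the ~1e-5 anchor tolerance
  expect_equal(csda_range_um(6.0, "tissue", tab), 48, tolerance = 1e-5)
  expect_equal(csda_range_um(7.69, "tissue", tab), 71, tolerance = 1e-5)
  expect_equal(csda_range_um(6.0, "air", tab), 4.6e4, tolerance = 1e-5)
  # independent Bragg-Kleeman oracle across the grid
  expect_equal(csda_range_um(tab$energy_MeV, "tissue", tab),
    oracle_bk_range_um(tab$energy_MeV), tolerance = 1e-9)
  # stopping power is dE/dx = 1 / (dR/dE)
  mid <- 100
  dE <- tab$energy_MeV[mid + 1] - tab$energy_MeV[mid - 1]
  dR <- tab$range_tissue_um[mid + 1] - tab$range_tissue_um[mid - 1]
  expect_equal(tab$S_tissue_MeV_um[mid], dE / dR, tolerance = 1e-3)
  expect_error(csda_range_um(10, "tissue", tab), "grid")
})

test_that("range inversion round-trips", {
  E <- c(0.5, 2, 6, 7.69)
  expect_equal(energy_at_range_um(csda_range_um(E, "tissue", tab),
    "tissue", tab), E, tolerance = 1e-6)
  expect_equal(energy_at_range_um(0, "tissue", tab), 0)
})

test_that("energy along a multi-medium track conserves energy", {
  segs <- tibble::tibble(
    medium = c("mucus", "air", "tissue"),
    length_um = c(9, 10000, 40)
  )
  out <- energy_along_track(segs, 7.69, tab)
  expect_equal(out$energy_in_MeV[1], 7.69)
  expect_equal(out$energy_in_MeV[-1], out$energy_out_MeV[-3], tolerance = 1e-9)
  expect_true(all(out$deposited_MeV >= 0))
  expect_lte(sum(out$deposited_MeV), 7.69 + 1e-9)
  # track that dies inside a segment deposits its full remaining energy
  short <- energy_along_track(
    tibble::tibble(medium = "tissue", length_um = 100), 6.0, tab)
  expect_equal(short$deposited_MeV, 6.0, tolerance = 1e-9)
  expect_error(energy_along_track(
    tibble::tibble(medium = "water", length_um = 1), 6), "unknown medium")
})

test_that("ray-ellipsoid chord matches the closed form", {
  # central ray through a sphere: chord = 2r
  ch <- ray_ellipsoid_chord(c(0, 0, -10), c(0, 0, 1), c(0, 0, 0), c(3, 3, 3))
  expect_equal(ch[2] - ch[1], 6, tolerance = 1e-9)
  expect_equal(ch[1], 7, tolerance = 1e-9)
  # off-centre ray through a sphere: chord = 2 sqrt(r^2 - b^2)
  b <- 1.5
  ch2 <- ray_ellipsoid_chord(c(b, 0, -10), c(0, 0, 1), c(0, 0, 0), c(3, 3, 3))
  expect_equal(ch2[2] - ch2[1], 2 * sqrt(9 - b^2), tolerance = 1e-9)
  # axis-scaled ellipsoid along y
  ch3 <- ray_ellipsoid_chord(c(0, -10, 0), c(0, 1, 0), c(0, 0, 0), c(1, 5, 2))
  expect_equal(ch3[2] - ch3[1], 10, tolerance = 1e-9)
  # miss and behind-the-origin cases
  expect_true(all(is.na(ray_ellipsoid_chord(c(10, 0, 0), c(0, 0, 1),
    c(0, 0, 0), c(1, 1, 1)))))
  expect_true(all(is.na(ray_ellipsoid_chord(c(0, 0, 10), c(0, 0, 1),
    c(0, 0, 0), c(1, 1, 1)))))
  # origin inside: entry clamps to 0
  ch4 <- ray_ellipsoid_chord(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0), c(2, 2, 2))
  expect_equal(ch4, c(0, 2), tolerance = 1e-9)
})

test_that("mean isotropic chord of a sphere is 4r/3", {
  set.seed(41)
  r <- 3
  n <- 20000
  # mu-randomness: entry points uniform on the surface, directions
  # cosine-weighted about the inward normal
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  nx <- sqrt(1 - z^2) * cos(phi)
  ny <- sqrt(1 - z^2) * sin(phi)
  nz <- z
  chords <- numeric(n)
  ct <- sqrt(runif(n)) # cosine-weighted polar angle about inward normal
  for (i in seq_len(n)) {
    p0 <- r * c(nx[i], ny[i], nz[i])
    inward <- -c(nx[i], ny[i], nz[i])
    # orthonormal frame around the inward normal
    a <- if (abs(inward[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- a - sum(a * inward) * inward
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(
      inward[2] * e1[3] - inward[3] * e1[2],
      inward[3] * e1[1] - inward[1] * e1[3],
      inward[1] * e1[2] - inward[2] * e1[1]
    )
    st <- sqrt(1 - ct[i]^2)
    psi <- runif(1, 0, 2 * pi)
    u <- ct[i] * inward + st * cos(psi) * e1 + st * sin(psi) * e2
    ch <- ray_ellipsoid_chord(p0, u, c(0, 0, 0), c(r, r, r))
    chords[i] <- ch[2] - ch[1]
  }
  expect_equal(mean(chords), 4 * r / 3, tolerance = 0.02)
})

test_that("epithelium model and nucleus sampling are geometrically sound", {
  ep <- epithelium_model()
  expect_equal(ep$types$type, c("secretory", "basal"))
  expect_equal(ep$gel_um + ep$sol_um, 9)
  set.seed(42)
  nuc <- sample_nuclei(ep, tile_mm = 1)
  # Poisson counts near the configured densities
  expect_equal(nrow(nuc), 1400, tolerance = 0.15)
  expect_true(all(nuc$x_um >= -500 & nuc$x_um <= 500))
  sec <- nuc[nuc$type == "secretory", ]
  bas <- nuc[nuc$type == "basal", ]
  expect_true(all(sec$depth_um >= 10 & sec$depth_um <= 40))
  expect_true(all(bas$depth_um >= 35 & bas$depth_um <= 50))
  expect_equal(unique(sec$ax_um), 4)
  # masses follow the ellipsoid volume
  expect_equal(nuc$mass_kg,
    4 / 3 * pi * nuc$ax_um * nuc$ay_um * nuc$az_um * 1e-18 * 1000)
})

test_that("nucleus doses respond to local events as expected", {
  set.seed(43)
  ep <- epithelium_model()
  nuc <- sample_nuclei(ep, tile_mm = 0.4)
  ev <- tibble::tibble(x_mm = 0, y_mm = 0, energy_MeV = 7.69, weight = 1)
  set.seed(43)
  dosed <- nucleus_doses(ev, nuc, ep, tab, n_tracks_per_event = 2000,
    tile_mm = 0.4, background_rate_per_mm2 = NULL)
  expect_true(all(dosed$dose_Gy >= 0))
  expect_gt(sum(dosed$hits), 0)
  # only nuclei within the tissue reach below the mucus can be hit:
  # 71 um total minus 9 um mucus leaves < 62 um of lateral reach
  hit <- dosed[dosed$hits > 0, ]
  expect_true(all(sqrt(hit$x_um^2 + hit$y_um^2) < 71))
  # dose scales linearly with event weight
  ev2 <- dplyr::mutate(ev, weight = 2)
  set.seed(43)
  dosed2 <- nucleus_doses(ev2, nuc, ep, tab, n_tracks_per_event = 2000,
    tile_mm = 0.4, background_rate_per_mm2 = NULL)
  expect_equal(dosed2$dose_Gy, 2 * dosed$dose_Gy, tolerance = 1e-9)
  # 6 MeV alphas reach the shallow secretory layer but spare deep basal
  # cells entirely below their maximal tissue penetration (48 um minus the
  # minimal 6.5 um mucus slant from the gel mid-depth emission)
  ev6 <- dplyr::mutate(ev, energy_MeV = 6.0)
  dosed6 <- nucleus_doses(ev6, nuc, ep, tab, n_tracks_per_event = 2000,
    tile_mm = 0.4, background_rate_per_mm2 = NULL)
  deep <- dosed6$depth_um - dosed6$az_um > 48 - 6.5
  expect_true(all(dosed6$dose_Gy[deep] == 0))
  # zero events, no background -> zero dose everywhere
  none <- nucleus_doses(ev[0, ], nuc, ep, tab,
    background_rate_per_mm2 = NULL)
  expect_true(all(none$dose_Gy == 0))
})

test_that("far-wall background arrivals dose the tile", {
  set.seed(44)
  ep <- epithelium_model()
  nuc <- sample_nuclei(ep, tile_mm = 0.4)
  dosed <- nucleus_doses(tibble::tibble(
    x_mm = numeric(), y_mm = numeric(), energy_MeV = numeric(),
    weight = numeric()
  ), nuc, ep, tab, n_tracks_per_event = 50, tile_mm = 0.4,
  background_rate_per_mm2 = 2000, background_energy_MeV = c(6, 7.69),
  lumen_diameter_cm = 0.45)
  expect_gt(sum(dosed$dose_Gy), 0)
  # far-wall tracks are heavily attenuated by the ~4.5 mm air crossing:
  # (4.5 mm air ~ 4.7 um tissue) so shallow nuclei still get hit
  expect_gt(sum(dosed$hits > 0), 0)
})
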