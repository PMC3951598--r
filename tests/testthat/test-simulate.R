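test_that("exposure is linear-additive with exact time-temperature equivalence", {
  cfg <- sim_config()
  expect_equal(exposure(baking_condition(10, 180), cfg), 10)
  expect_equal(exposure(baking_condition(9, 190), cfg), 10)
  expect_equal(exposure(baking_condition(4, 150), cfg), 1)
  # dE/dt : dE/dT = temp_per_min_equiv exactly, everywhere
  de_dt <- exposure(baking_condition(8 + 1e-3, 170), cfg) -
    exposure(baking_condition(8, 170), cfg)
  de_dT <- exposure(baking_condition(8, 170 + 1e-3), cfg) -
    exposure(baking_condition(8, 170), cfg)
  expect_equal(de_dt / de_dT, cfg$temp_per_min_equiv, tolerance = 1e-9)
  expect_error(baking_condition(0, 180), "positive|> 0")
})

test_that("drying curve has the stated closed form and calibrated extremes", {
  cfg <- sim_config()
  expect_equal(water_curve(0, cfg), cfg$water_initial_frac)
  expect_equal(water_curve(1e6, cfg), cfg$water_floor_frac, tolerance = 1e-12)
  expect_equal(
    water_curve(cfg$water_decay_tau, cfg),
    cfg$water_floor_frac +
      (cfg$water_initial_frac - cfg$water_floor_frac) / exp(1)
  )
  expect_true(all(diff(water_curve(seq(0, 20, 0.5), cfg)) < 0))
  # negative exposures clamp to the unbaked state
  expect_equal(water_curve(-3, cfg), cfg$water_initial_frac)
  # design-extreme calibration: the full grid spans ~1.2-9.4 % water
  e_min <- exposure(baking_condition(4, 150), cfg)
  e_max <- exposure(baking_condition(16, 200), cfg)
  expect_gt(water_curve(e_min, cfg), 0.090)
  expect_lt(water_curve(e_min, cfg), 0.096)
  expect_gt(water_curve(e_max, cfg), 0.009)
  expect_lt(water_curve(e_max, cfg), 0.012)
})

test_that("rendering is deterministic, clipped, and radially graded", {
  cfg <- tiny_cfg(noise_sd = 0)
  # unbaked limit: every cookie pixel equals the dough base spectrum
  r0 <- render_image(baking_condition(1e-9, 180), cfg, seed = 3)
  b395 <- which.min(abs(cfg$wavelengths_nm - 395))
  base <- r0$image$cube[cfg$image_size / 2, cfg$image_size / 2, ]
  px <- which(r0$image$mask, arr.ind = TRUE)
  for (b in seq_along(cfg$wavelengths_nm)) {
    vals <- r0$image$cube[, , b][r0$image$mask]
    expect_equal(max(abs(vals - base[b])), 0)
  }

  # edge browner than center at 395 nm, matching the stated formula
  ri <- render_image(baking_condition(8, 180), cfg, seed = 3)
  ctr <- (cfg$image_size + 1) / 2
  center_val <- ri$image$cube[round(ctr), round(ctr), b395]
  edge_val <- ri$image$cube[round(ctr), round(ctr) + cfg$cookie_radius_px - 1, b395]
  expect_lt(edge_val, center_val)
  # oracle: evaluate the stated attenuation formula at both radii;
  # odd image size puts a pixel exactly at the disk center (rho = 0)
  cfg0 <- tiny_cfg(noise_sd = 0, water_jitter_sd = 0, image_size = 47L)
  ri0 <- render_image(baking_condition(8, 180), cfg0, seed = 3)
  ctr0 <- (cfg0$image_size + 1) / 2
  rho_edge <- (cfg0$cookie_radius_px - 1) / cfg0$cookie_radius_px
  for (rho in c(0, rho_edge)) {
    e_loc <- 8 * (cfg0$edge_lead + (1 - cfg0$edge_lead) * rho)
    expected <- (0.48 + 0.17 * plogis((395 - 540) / 70)) *
      exp(-cfg0$pigment_rate * e_loc * cfg0$brown_absorb_template[b395]) *
      exp(-(water_curve(e_loc, cfg0) - cfg0$water_initial_frac) *
            cfg0$water_absorb_template[b395])
    got <- if (rho == 0) ri0$image$cube[ctr0, ctr0, b395] else
      ri0$image$cube[ctr0, ctr0 + cfg0$cookie_radius_px - 1, b395]
    expect_equal(got, expected, tolerance = 1e-10)
  }

  # determinism and clipping
  cfgn <- tiny_cfg(noise_sd = 0.05)
  a <- render_image(baking_condition(12, 200), cfgn, seed = 11)
  b <- render_image(baking_condition(12, 200), cfgn, seed = 11)
  expect_identical(a$image$cube, b$image$cube)
  expect_true(all(a$image$cube >= 0 & a$image$cube <= 1))
  expect_error(
    render_image(baking_condition(8, 180),
                 sim_config(image_size = 32L, cookie_radius_px = 16L)),
    "radius"
  )
})

test_that("mean cookie spectra are non-increasing in baking time at every band", {
  cfg <- tiny_cfg(noise_sd = 0, water_jitter_sd = 0)
  times <- c(4, 6, 7, 8, 9, 10, 12, 14, 16, 20)
  spectra <- t(vapply(times, function(t) {
    ri <- render_image(baking_condition(t, 180), cfg, seed = 1)
    mean_spectrum(ri$image)
  }, numeric(length(cfg$wavelengths_nm))))
  expect_true(all(apply(spectra, 2, function(col) all(diff(col) <= 1e-12))))
  # and pixel-level browning is monotone in radius
  ri <- render_image(baking_condition(10, 180), cfg, seed = 1)
  ctr <- (cfg$image_size + 1) / 2
  b395 <- which.min(abs(cfg$wavelengths_nm - 395))
  profile <- ri$image$cube[round(ctr), round(ctr):(round(ctr) + cfg$cookie_radius_px - 1), b395]
  expect_true(all(diff(profile) <= 1e-12))
})

test_that("gravimetry round-trips the water fraction and is unbiased", {
  g <- simulate_gravimetry(list(water_frac_true = 0.10), 10, noise_sd_g = 0)
  expect_equal(unname(g), c(10, 9))
  g0 <- simulate_gravimetry(list(water_frac_true = 0), 10, noise_sd_g = 0)
  expect_equal(g0[["dried_mass_g"]], g0[["initial_mass_g"]])
  # Monte-Carlo: recovered fraction unbiased within 3 SE at 0.005 g noise
  x <- vapply(1:1000, function(s) {
    m <- simulate_gravimetry(list(water_frac_true = 0.05), 10, 0.005, seed = s)
    (m[["initial_mass_g"]] - m[["dried_mass_g"]]) / m[["initial_mass_g"]]
  }, numeric(1))
  expect_lt(abs(mean(x) - 0.05), 3 * sd(x) / sqrt(length(x)))
})

test_that("panel votes are conserved, thresholded, and never span both extremes", {
  v <- simulate_panel(2, n_panelists = 6, vote_noise = 0)
  expect_equal(unname(v), c(6, 0, 0))
  expect_equal(sum(simulate_panel(8.7, n_panelists = 6, vote_noise = 1.5, seed = 4)), 6)
  expect_error(simulate_panel(8, thresholds = c(11, 5)), "increasing")
  # the reference-temperature time series at zero noise: 4 min underbaked,
  # 6-10 min adequate, >= 12 min overbaked, no under+over conflicts
  times <- c(4, 6, 7, 8, 9, 10, 12, 14, 16, 20)
  votes <- t(vapply(times, function(t) simulate_panel(t, 6, vote_noise = 0),
                    integer(3)))
  expect_equal(consensus_class(votes),
               c("underbaked", rep("adequately_baked", 5), rep("overbaked", 4)))
  expect_true(all(votes[, 1] == 0 | votes[, 3] == 0))
})

test_that("generated designs have the right layout and are seed-reproducible", {
  cfg <- tiny_cfg(image_size = 32L)
  s1 <- fixture_set1()
  expect_equal(nrow(s1$records), 30)
  expect_true(all(s1$records$temp_c == 180))
  expect_equal(sort(unique(s1$records$time_min)),
               c(4, 6, 7, 8, 9, 10, 12, 14, 16, 20))

  s2 <- fixture_set2()
  expect_equal(nrow(s2$records), 105)
  expect_equal(sort(unique(s2$records$temp_c)), c(150, 160, 170, 180, 200))
  expect_equal(sort(unique(s2$records$time_min)), c(4, 6, 8, 10, 12, 14, 16))
  expect_true(all(s2$records$dried_mass_g <= s2$records$initial_mass_g))
  expect_true(all(s2$truth$water_frac_true >= cfg$water_floor_frac &
                    s2$truth$water_frac_true <= cfg$water_initial_frac))
  expect_error(generate_set("set3", cfg), "arg")

  a <- generate_set("set1", cfg, seed = 42)
  b <- generate_set("set1", cfg, seed = 42)
  expect_identical(a, b)
})
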