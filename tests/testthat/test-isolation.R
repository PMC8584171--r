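test_that("water concentration follows volume additivity with guards", {
  wm <- water_model(vbar_nma = 0.077, vbar_osm = 0.072)
  expect_equal(water_concentration(0, 0, wm), 55.345)
  # zero partial molar volumes: constant water for all compositions
  wm0 <- water_model()
  expect_equal(water_concentration(c(0, 1, 2), c(2, 1, 0), wm0),
               rep(55.345, 3))
  # occupied volume >= total volume is nonphysical
  expect_error(water_concentration(10, 10, wm), "nonphysical")
  expect_error(water_concentration(-1, 0, wm), "non-negative")
})

test_that("water subtraction removes the water contribution exactly", {
  sim <- ideal_scenario(seed = 6, noise_sd = 0, jitter_sd = 0)
  tr <- sim$truth
  tg <- default_target_grid(sim$set)
  grid <- interpolate_grid(sim$set, tg)
  gw <- subtract_water(grid, tr$water_ref, tr$water)
  # the pure-water node must become the zero spectrum
  expect_lt(max(abs(gw$tensor[, 1, 1])), 1e-12)
  # remaining signal is the two solute contributions
  for (i in c(2, 5)) for (j in c(1, 4)) {
    truth <- tg$c1_levels[i] * tr$components$nma$epsilon +
      tg$c2_levels[j] * tr$components$osmolyte$epsilon
    expect_lt(max(abs(gw$tensor[, i, j] - truth)), 1e-10)
  }
})

test_that("vbar = 0 reduces to subtracting one scaled water spectrum", {
  sim <- ideal_scenario(seed = 6, noise_sd = 0, jitter_sd = 0)
  grid <- interpolate_grid(sim$set, default_target_grid(sim$set))
  gw <- subtract_water(grid, sim$truth$water_ref, water_model())
  manual <- sweep(grid$tensor, 1, sim$truth$water_ref$absorbance, "-")
  expect_equal(gw$tensor, manual, tolerance = 1e-12)
})

test_that("component estimation recovers planted molar absorptivities", {
  sim <- ideal_scenario(seed = 10, noise_sd = 0, jitter_sd = 0.01)
  conc <- sim$set$concentrations
  binary <- subset_spectra(sim$set, conc$c_osm == 0)
  est <- estimate_component_spectrum(binary, sim$truth$water_ref,
                                     sim$truth$water, "nma")
  expect_lt(max(abs(est$epsilon - sim$truth$components$nma$epsilon)),
            1e-10)
})

test_that("self-association biases the slope by k * sum(c^3)/sum(c^2)", {
  sim <- stabilizer_scenario(seed = 10, noise_sd = 0, jitter_sd = 0)
  tr <- sim$truth
  conc <- sim$set$concentrations
  binary <- subset_spectra(sim$set, conc$c_osm == 0)
  est <- estimate_component_spectrum(binary, tr$water_ref, tr$water,
                                     "nma")
  cc <- binary$concentrations$c_nma
  cc <- cc[cc > 0]
  predicted <- tr$components$nma$epsilon +
    tr$k_self_nma * (sum(cc^3) / sum(cc^2)) * tr$self_shape_nma
  expect_lt(max(abs(est$epsilon - predicted)), 1e-12)

  # cross-check against brute-force through-origin normal equations
  resid <- binary$absorbance -
    outer(tr$water_ref$absorbance / 55.345,
          water_concentration(binary$concentrations$c_nma, 0, tr$water))
  keep <- binary$concentrations$c_nma > 0
  oracle <- oracle_origin_slope(resid[, keep, drop = FALSE],
                                binary$concentrations$c_nma[keep])
  expect_lt(max(abs(est$epsilon - oracle)), 1e-12)
})

test_that("estimation preconditions are enforced", {
  sim <- ideal_scenario(seed = 1, jitter_sd = 0)
  conc <- sim$set$concentrations
  mixed <- subset_spectra(sim$set, conc$c_osm > 0)
  expect_error(estimate_component_spectrum(mixed, sim$truth$water_ref,
                                           sim$truth$water, "nma"),
               "zero concentration")
  tiny <- subset_spectra(sim$set, conc$c_osm == 0 & conc$c_nma <= 0.4)
  expect_error(estimate_component_spectrum(tiny, sim$truth$water_ref,
                                           sim$truth$water, "nma"),
               "3 distinct")
})

test_that("complete subtraction of an ideal mixture leaves nothing", {
  sim <- ideal_scenario(seed = 13, noise_sd = 0, jitter_sd = 0.01)
  tr <- sim$truth
  grid <- interpolate_grid(sim$set, default_target_grid(sim$set))
  gw <- subtract_water(grid, tr$water_ref, tr$water)
  g1 <- subtract_solute(gw, tr$components$nma, "nma")
  g2 <- subtract_solute(g1, tr$components$osmolyte, "osmolyte")
  expect_lt(max(abs(g2$tensor)), 1e-10)

  # subtracting a zero component is the identity
  zero <- component_spectrum(grid$wavenumbers,
                             numeric(length(grid$wavenumbers)), "nma")
  expect_warning(est0 <- zero, NA)
  expect_equal(subtract_solute(gw, zero, "nma")$tensor, gw$tensor)

  # axis bookkeeping is untouched by isolation
  expect_identical(g2$wavenumbers, grid$wavenumbers)
  expect_identical(g2$c1_levels, grid$c1_levels)
})

test_that("component and axis mismatches are errors", {
  sim <- ideal_scenario(seed = 1, jitter_sd = 0)
  grid <- interpolate_grid(sim$set, default_target_grid(sim$set))
  gw <- subtract_water(grid, sim$truth$water_ref, sim$truth$water)
  expect_error(subtract_solute(gw, sim$truth$components$nma, "osmolyte"),
               "axis")
  short_ref <- ftir_spectrum(grid$wavenumbers[-1],
                             sim$truth$water_ref$absorbance[-1])
  expect_error(subtract_water(grid, short_ref, sim$truth$water), "axis")
})

test_that("sequential subtraction equals one combined subtraction", {
  sim <- stabilizer_scenario(seed = 4, noise_sd = 1e-3, jitter_sd = 0.01)
  tr <- sim$truth
  grid <- interpolate_grid(sim$set, default_target_grid(sim$set))
  gw <- subtract_water(grid, tr$water_ref, tr$water)
  seq2 <- subtract_solute(gw, tr$components$nma, "nma")
  cw <- outer(grid$c1_levels, grid$c2_levels,
              function(a, b) water_concentration(a, b, tr$water))
  combined <- grid$tensor -
    outer(tr$water_ref$absorbance, cw / 55.345) -
    outer(tr$components$nma$epsilon,
          matrix(grid$c1_levels, 5, 5))
  expect_lt(max(abs(seq2$tensor - combined)), 1e-12)
})

test_that("over-strict subtraction produces a difference band", {
  # subtracting a slightly shifted component spectrum must leave a
  # derivative-shaped residual that changes sign at the band center
  w <- test_axis(1300, 1700, 2)
  eps <- gauss(w, 1500, 15, 0.3)
  eps_shifted <- gauss(w, 1502, 15, 0.3)
  c1 <- c(0.5, 1, 1.5); c2 <- c(0, 1)
  grid <- spectra_grid(w, c1, c2,
                       outer(eps, matrix(c1, 3, 2)))
  g <- subtract_solute(grid, component_spectrum(w, eps_shifted, "nma"),
                       "nma")
  resid <- g$tensor[, 2, 1]
  center <- which.min(abs(w - 1500))
  expect_lt(resid[center - 5] * resid[center + 5], 0)
})
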