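make_binary <- function(k_self = 0, noise = 0, seed = 1) {
  # water-subtracted binary NMA series with optional self-association
  w <- test_axis(1300, 1700, 2)
  eps <- gauss(w, 1620, 14, 0.3) + gauss(w, 1420, 10, 0.1)
  s <- gauss(w, 1640, 9) - gauss(w, 1600, 9)
  cc <- seq(0.4, 2, by = 0.4)
  A <- outer(eps, cc) + k_self * outer(s, cc^2)
  if (noise > 0) {
    set.seed(seed)
    A <- A + matrix(rnorm(length(A), 0, noise), nrow(A))
  }
  list(set = scattered_spectra(w, A, data.frame(c_nma = cc, c_osm = 0)),
       eps = eps, s = s, cc = cc, A = A)
}

test_that("ideal Beer-Lambert series has a zero derivative spectrum", {
  b <- make_binary(k_self = 0)
  d <- derivative_spectrum(b$set, "nma")
  expect_lt(max(abs(d$d_molar_absorbance)), 1e-12)
})

test_that("self-association gives derivative k_self * s exactly", {
  b <- make_binary(k_self = 0.03)
  d <- derivative_spectrum(b$set, "nma")
  expect_lt(max(abs(d$d_molar_absorbance - 0.03 * b$s)), 1e-10)

  # brute-force oracle: per-wavenumber lm of molar absorbance on c
  molar <- sweep(b$A, 2, b$cc, "/")
  oracle <- oracle_ls_slope(molar, b$cc)
  expect_lt(max(abs(d$d_molar_absorbance - oracle)), 1e-12)
  expect_equal(d$concentration_range, c(0.4, 2))
})

test_that("the derivative is linear in the absorbances", {
  b <- make_binary(k_self = 0.02)
  d1 <- derivative_spectrum(b$set, "nma")
  doubled <- b$set
  doubled$absorbance <- 2 * doubled$absorbance
  d2 <- derivative_spectrum(doubled, "nma")
  expect_equal(d2$d_molar_absorbance, 2 * d1$d_molar_absorbance,
               tolerance = 1e-12)
})

test_that("zero concentrations are excluded with a message, few levels error", {
  b <- make_binary()
  with0 <- b$set
  w <- with0$wavenumbers
  with0 <- scattered_spectra(
    w, cbind(b$A, 0),
    rbind(b$set$concentrations[, c("c_nma", "c_osm")],
          data.frame(c_nma = 0, c_osm = 0)))
  expect_message(d <- derivative_spectrum(with0, "nma"), "excluded")
  d0 <- derivative_spectrum(b$set, "nma")
  expect_equal(d$d_molar_absorbance, d0$d_molar_absorbance)

  two <- subset_spectra(b$set, 1:2)
  expect_error(derivative_spectrum(two, "nma"), "3 distinct")
  mixed <- b$set
  mixed$concentrations$c_osm <- 1
  expect_error(derivative_spectrum(mixed, "nma"), "binary")
})

test_that("congruence matching behaves at the three anchor cases", {
  b <- make_binary(k_self = 0.03)
  d <- derivative_spectrum(b$set, "nma")
  expect_equal(match_factor_to_derivative(d$d_molar_absorbance, d), 1.0)
  expect_equal(match_factor_to_derivative(-d$d_molar_absorbance, d),
               -1.0)
  # disjoint band supports are orthogonal by construction
  w <- b$set$wavenumbers
  far <- gauss(w, 1330, 5)
  expect_lt(abs(match_factor_to_derivative(far, d)), 1e-12)
  expect_equal(sum(far * d$d_molar_absorbance), 0, tolerance = 1e-12)
  expect_error(tucker_congruence(numeric(10), rnorm(10)), "zero-norm")
})

test_that("derivative invariance to pre-subtraction water offsets", {
  # adding a water multiple before redoing the water subtraction must
  # not change the derivative
  sim <- stabilizer_scenario(seed = 2, noise_sd = 0, jitter_sd = 0)
  tr <- sim$truth
  conc <- sim$set$concentrations
  binary <- subset_spectra(sim$set, conc$c_osm == 0)
  d1 <- derivative_spectrum(
    suppressMessages(subtract_water(binary, tr$water_ref, tr$water)),
    "nma")
  shifted <- binary
  shifted$absorbance <- shifted$absorbance +
    outer(tr$water_ref$absorbance,
          water_concentration(conc$c_nma[conc$c_osm == 0], 0,
                              tr$water) / 55.345)
  twice <- subtract_water(
    subtract_water(shifted, tr$water_ref, tr$water),
    tr$water_ref, tr$water)
  d2 <- derivative_spectrum(twice, "nma")
  expect_lt(max(abs(d1$d_molar_absorbance - d2$d_molar_absorbance)),
            1e-10)
})

test_that("the stabilizer concentration-change factor matches the derivative", {
  rep <- run_scenario("stabilizer", seed = 3, noise_sd = 0,
                      jitter_sd = 0, n_restarts = 3)
  lab <- rep$nma_isolated$labels
  k <- which(lab$label == "concentration_change")
  expect_length(k, 1)
  cg <- match_factor_to_derivative(rep$nma_isolated$model$A[, k],
                                   rep$derivatives$nma)
  expect_gte(abs(cg), 0.99)
})
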