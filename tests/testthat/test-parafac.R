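test_that("rank-1 tensors are recovered exactly with conventions", {
  w <- test_axis(1300, 1700, 2)
  a <- gauss(w, 1500, 20, 0.4)
  b <- c(0.2, 0.5, 1, 1.5, 2)
  cc <- c(1, 0.8, 0.6, 0.4)
  X <- oracle_cp_tensor(cbind(a), cbind(b), cbind(cc))
  m <- cp_als(X, rank = 1, seed = 1, n_restarts = 3)
  expect_lt(m$rel_error, 1e-10)
  # unit-norm concentration loadings with positive dominant entries
  expect_equal(sum(m$B^2), 1, tolerance = 1e-12)
  expect_equal(sum(m$C^2), 1, tolerance = 1e-12)
  expect_gt(m$B[which.max(abs(m$B)), 1], 0)
  expect_gt(m$C[which.max(abs(m$C)), 1], 0)
  # loadings match up to the scale convention
  expect_gt(abs(tucker_congruence(m$A[, 1], a)), 1 - 1e-10)
  expect_gt(abs(tucker_congruence(m$B[, 1], b)), 1 - 1e-10)
  expect_lt(max(abs(cp_reconstruct(m) - X)), 1e-10)
})

test_that("planted rank-3 factors are recovered to congruence 0.999", {
  pl <- make_planted3(P = 200, I = 5, J = 5)
  m <- cp_als(pl$tensor, rank = 3, seed = 2, n_restarts = 5,
              tol = 1e-12, max_iter = 4000)
  expect_lt(m$rel_error, 1e-8)
  matched <- match_factors(m$A, pl$A)
  expect_gte(min(matched$congruence), 0.999)
  # two best restarts agree on noise-free data
  expect_gte(m$restart_congruence, 0.999)
})

test_that("scaling the tensor scales only the spectral mode", {
  pl <- make_planted3(P = 60)
  m1 <- cp_als(pl$tensor, rank = 3, seed = 5, n_restarts = 2)
  m2 <- cp_als(3.5 * pl$tensor, rank = 3, seed = 5, n_restarts = 2)
  p <- match_factors(m2$A, m1$A)$perm
  expect_lt(max(abs(m2$A[, p] - 3.5 * m1$A)), 1e-8)
  expect_lt(max(abs(abs(m2$B[, p]) - abs(m1$B))), 1e-10)
  expect_lt(max(abs(abs(m2$C[, p]) - abs(m1$C))), 1e-10)
})

test_that("the ALS loss never increases across reported sweeps", {
  pl <- make_planted3(P = 80)
  set.seed(99)
  noisy <- pl$tensor + array(rnorm(length(pl$tensor), 0, 1e-3),
                             dim(pl$tensor))
  for (rank in 2:4) {
    m <- cp_als(noisy, rank = rank, seed = 7, n_restarts = 2,
                max_iter = 300)
    expect_true(all(diff(m$rel_error_trace) <= 1e-12))
    expect_true(m$rel_error >= 0 && m$rel_error <= 1)
  }
})

test_that("degenerate inputs are rejected", {
  pl <- make_planted3(P = 20)
  expect_error(cp_als(pl$tensor, rank = 0), "rank")
  expect_error(cp_als(array(0, c(5, 4, 3)), rank = 1), "zero")
  bad <- pl$tensor; bad[1] <- NA
  expect_error(cp_als(bad, rank = 1), "finite")
  expect_error(cp_als(array(1, c(5, 1, 3)), rank = 1), "2 levels")
})

test_that("factor congruence equals brute-force normalized dot products", {
  set.seed(17)
  M1 <- matrix(rnorm(30), 10, 3); M2 <- matrix(rnorm(30), 10, 3)
  cg <- factor_congruence(M1, M2)
  for (r in 1:3) for (s in 1:3) {
    expect_equal(cg[r, s],
                 sum(M1[, r] * M2[, s]) /
                   sqrt(sum(M1[, r]^2) * sum(M2[, s]^2)))
  }
  # orthonormal self-congruence is the identity
  Q <- qr.Q(qr(M1))
  expect_equal(factor_congruence(Q, Q), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(factor_congruence(cbind(M1[, 1]), cbind(-M1[, 1]))[1, 1],
               -1)
  expect_error(factor_congruence(cbind(numeric(10)), M2), "zero-norm")
})

test_that("rank selection stops before r_max on exactly low-rank data", {
  pl <- make_planted3(P = 100)
  X2 <- oracle_cp_tensor(pl$A[, 1:2], pl$B[, 1:2], pl$C[, 1:2])
  scan <- select_rank(X2, r_min = 2, r_max = 4, seed = 3,
                      n_restarts = 3)
  expect_equal(scan$chosen_rank, 2)
  expect_false(scan$stopping_reason == "r_max_reached")
  expect_error(select_rank(X2, r_min = 3, r_max = 2), "r_max")
  expect_error(select_rank(X2, r_min = 1), "r_min")
})

test_that("rank selection finds the planted rank of scenario tensors", {
  for (case in list(list(sc = "stabilizer", rank = 2),
                    list(sc = "denaturant", rank = 3))) {
    rep <- run_scenario(case$sc, seed = 21, noise_sd = 0, jitter_sd = 0)
    expect_equal(rep$nma_isolated$scan$chosen_rank, case$rank,
                 label = case$sc)
    expect_equal(rep$osm_isolated$scan$chosen_rank, case$rank,
                 label = case$sc)
  }
})

test_that("classification anchors: a factor equal to a reference", {
  w <- test_axis(1300, 1700, 2)
  eps <- gauss(w, 1620, 14, 0.3)
  s <- gauss(w, 1640, 9) - gauss(w, 1600, 9)
  comp <- component_spectrum(w, eps, "nma")
  b <- c(0.4, 0.8, 1.2, 1.6, 2)
  X <- oracle_cp_tensor(cbind(eps, 0.02 * s), cbind(b, b^2),
                        cbind(rep(1, 4), rep(1, 4)))
  m <- cp_als(X, rank = 2, seed = 1, n_restarts = 3)
  m <- resolve_degeneracy(m, list(comp$epsilon, s))
  dfake <- structure(list(wavenumbers = w, d_molar_absorbance = s,
                          solute_name = "nma",
                          concentration_range = c(0.4, 2)),
                     class = "derivative_spectrum")
  lab <- classify_factors(m, comp, dfake)
  expect_setequal(lab$label, c("pure_component", "concentration_change"))
  pure <- lab[lab$label == "pure_component", ]
  expect_equal(pure$congruence_pure, 1, tolerance = 1e-6)
})

test_that("unresolved degenerate pairs are surfaced, then fixed by rotation", {
  # two factors sharing one concentration mode: CP alone cannot split
  # them; resolve_degeneracy with both references must
  w <- test_axis(1300, 1700, 2)
  a1 <- gauss(w, 1620, 14, 0.3); a2 <- gauss(w, 1640, 9) -
    gauss(w, 1600, 9)
  b <- c(0.4, 0.8, 1.2, 1.6, 2)
  X <- oracle_cp_tensor(cbind(a1, a2), cbind(b, b^2),
                        cbind(rep(1, 5), rep(1, 5)))
  m <- cp_als(X, rank = 2, seed = 6, n_restarts = 3)
  expect_lt(m$rel_error, 1e-9)
  m2 <- resolve_degeneracy(m, list(a1, a2))
  cg <- abs(factor_congruence(m2$A, cbind(a1, a2)))
  best <- match_factors(m2$A, cbind(a1, a2))
  expect_gte(min(best$congruence), 1 - 1e-6)
  # the reconstruction is untouched by the rotation
  expect_lt(max(abs(cp_reconstruct(m2) - X)), 1e-8)
})
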