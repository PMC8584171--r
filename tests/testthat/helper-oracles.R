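# Shared fixtures and independent oracles. Everything here is built in
# code at test time; oracles deliberately avoid the package's own code
# paths (plain lm()/solve() normal equations, direct formula
# evaluation) so they can falsify the implementation.

test_axis <- function(from = 1300, to = 1700, by = 4) seq(from, to, by = by)

gauss <- function(w, center, sigma, height = 1) {
  height * exp(-(w - center)^2 / (2 * sigma^2))
}

# through-origin least-squares slope per wavenumber, brute force
oracle_origin_slope <- function(A, conc) {
  apply(A, 1, function(y) {
    X <- matrix(conc, ncol = 1)
    drop(solve(t(X) %*% X, t(X) %*% y))
  })
}

# ordinary least-squares slope (with intercept) per row, brute force
oracle_ls_slope <- function(A, conc) {
  apply(A, 1, function(y) unname(stats::coef(stats::lm(y ~ conc))[2]))
}

# rank-R tensor from explicit loadings, direct triple loop free
oracle_cp_tensor <- function(A, B, C) {
  P <- nrow(A); I <- nrow(B); J <- nrow(C)
  X <- array(0, c(P, I, J))
  for (r in seq_len(ncol(A))) {
    X <- X + outer(A[, r], outer(B[, r], C[, r]))
  }
  X
}

# planted rank-3 tensor with well-separated (identifiable) loadings
make_planted3 <- function(P = 200, I = 5, J = 5, seed = 42) {
  w <- seq(1300, 1700, length.out = P)
  A <- cbind(gauss(w, 1620, 15, 0.3),
             gauss(w, 1450, 12, 0.2) - gauss(w, 1420, 12, 0.2),
             gauss(w, 1550, 10, 0.25))
  set.seed(seed)
  B <- cbind(seq(0.2, 1, length.out = I),
             seq(1, 0.3, length.out = I)^2,
             0.5 + cos(seq(0, pi, length.out = I)) * 0.4)
  C <- cbind(seq(1, 0.2, length.out = J),
             0.4 + seq(0, 1, length.out = J)^2,
             seq(0.2, 1, length.out = J))
  list(wavenumbers = w, A = A, B = B, C = C,
       tensor = oracle_cp_tensor(A, B, C))
}

# ideal affine absorbance field evaluated at scattered points
affine_set <- function(a0 = 0.1, a1 = 0.2, a2 = 0.3, n = 30,
                       seed = 7, P = 15) {
  set.seed(seed)
  w <- test_axis(1400, 1400 + 4 * (P - 1))
  conc <- data.frame(c_nma = runif(n, 0, 2), c_osm = runif(n, 0, 2))
  conc$c_nma[1:4] <- c(0, 2, 0, 2); conc$c_osm[1:4] <- c(0, 0, 2, 2)
  shapes <- cbind(gauss(w, 1450, 20), gauss(w, 1500, 15),
                  gauss(w, 1550, 18))
  A <- shapes %*% rbind(a0 + 0 * conc$c_nma, a1 * conc$c_nma,
                        a2 * conc$c_osm)
  list(set = scattered_spectra(w, A, conc),
       eval = function(c1, c2, shape = 1) {
         drop(shapes %*% c(a0, a1 * c1, a2 * c2))
       })
}

# scaled pipeline settings used throughout the tests: restart and
# iteration counts chosen for the small 5x5x276 problem sizes
run_scenario <- function(scenario, seed, noise_sd, jitter_sd,
                         n_restarts = 6, max_iter = 600, ...) {
  run_pipeline(pipeline_config(scenario = scenario, seed = seed,
                               noise_sd = noise_sd,
                               jitter_sd = jitter_sd,
                               n_restarts = n_restarts,
                               max_iter = max_iter, ...))
}
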