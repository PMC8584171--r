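# Unconstrained CP (PARAFAC) decomposition of the isolated three-way
# spectra tensors by alternating least squares, with the normalization
# and sign conventions that make factor spectra directly comparable to
# measured component and derivative spectra, plus the incremental
# rank-selection procedure based on factor redundancy.
#
# Model: X[p,i,j] ~ sum_r A[p,r] * B[i,r] * C[j,r]
# with mode order wavenumber x c_nma level x c_osm level. Non-negative
# variants are deliberately not offered: negative (difference) bands
# are expected and meaningful in isolated spectra.

# Khatri-Rao (column-wise Kronecker); rows of V vary fastest.
khatri_rao <- function(U, V) {
  U[rep(seq_len(nrow(U)), each = nrow(V)), , drop = FALSE] *
    V[rep(seq_len(nrow(V)), times = nrow(U)), , drop = FALSE]
}

new_cp_model <- function(rank, wavenumbers, A, B, C, rel_error,
                         n_iterations, converged,
                         restart_congruence = NA_real_,
                         rel_error_trace = NULL) {
  structure(list(rank = rank, wavenumbers = wavenumbers,
                 A = A, B = B, C = C,
                 rel_error = rel_error, n_iterations = n_iterations,
                 converged = converged,
                 restart_congruence = restart_congruence,
                 rel_error_trace = rel_error_trace),
            class = "cp_model")
}

#' @export
print.cp_model <- function(x, ...) {
  cat(sprintf(
    "CP model, rank %d: rel_error = %.3g after %d iterations (%s)\n",
    x$rank, x$rel_error, x$n_iterations,
    if (isTRUE(x$converged)) "converged" else "not converged"))
  if (is.finite(x$restart_congruence)) {
    cat(sprintf("  restart stability (matched congruence): %.4f\n",
                x$restart_congruence))
  }
  invisible(x)
}

# enforce: unit-norm B/C columns, scale in A, max-|entry| of each
# B and C column positive
apply_conventions <- function(A, B, C) {
  for (r in seq_len(ncol(A))) {
    nb <- sqrt(sum(B[, r]^2)); nc <- sqrt(sum(C[, r]^2))
    if (nb == 0 || nc == 0) next
    B[, r] <- B[, r] / nb; C[, r] <- C[, r] / nc
    A[, r] <- A[, r] * nb * nc
    sb <- sign(B[which.max(abs(B[, r])), r])
    if (sb < 0) { B[, r] <- -B[, r]; A[, r] <- -A[, r] }
    sc <- sign(C[which.max(abs(C[, r])), r])
    if (sc < 0) { C[, r] <- -C[, r]; A[, r] <- -A[, r] }
  }
  list(A = A, B = B, C = C)
}

# ridge-regularised solve of the ALS normal equations M G^-1; the
# ridge scales with the Gram diagonal and escalates if a factor has
# collapsed to (near) zero norm and left G singular
solve_gram <- function(M, G, ridge) {
  s <- max(diag(G), .Machine$double.xmin)
  r <- ridge
  repeat {
    Gr <- G + diag(r * s, ncol(G))
    ok <- tryCatch(rcond(Gr) > 1e-15, error = function(e) FALSE)
    if (ok) return(t(solve(Gr, t(M))))
    r <- r * 100
    if (r > 1) stop_ternafac("normal equations irreparably singular")
  }
}

als_single <- function(X1, X2, X3, dims, rank, init, max_iter, tol,
                       ridge, normX) {
  A <- init$A; B <- init$B; C <- init$C
  rel_trace <- numeric(0)
  rel_prev <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    A0 <- A; B0 <- B; C0 <- C
    # mode updates by Khatri-Rao normal equations
    Z <- khatri_rao(C, B)
    A <- solve_gram(X1 %*% Z, crossprod(B) * crossprod(C), ridge)
    Z <- khatri_rao(C, A)
    B <- solve_gram(X2 %*% Z, crossprod(A) * crossprod(C), ridge)
    Z <- khatri_rao(B, A)
    C <- solve_gram(X3 %*% Z, crossprod(A) * crossprod(B), ridge)
    resid <- X1 - A %*% t(khatri_rao(C, B))
    rel <- sqrt(sum(resid^2)) / normX
    if (rel > rel_prev) {
      # a full LS sweep cannot increase the loss; an increase means the
      # conditioning ridge dominates at the numerical floor -- keep the
      # previous iterate and stop
      A <- A0; B <- B0; C <- C0
      converged <- TRUE
      break
    }
    rel_trace <- c(rel_trace, rel)
    if (is.finite(rel_prev) && rel_prev - rel < tol) {
      converged <- TRUE
      break
    }
    if (rel < 1e-14) { converged <- TRUE; break }
    rel_prev <- rel
  }
  if (!length(rel_trace)) {
    rel_trace <- sqrt(sum((X1 - A %*% t(khatri_rao(C, B)))^2)) / normX
  }
  list(A = A, B = B, C = C, rel_error = rel_trace[length(rel_trace)],
       n_iterations = it, converged = converged,
       rel_error_trace = rel_trace)
}

random_init <- function(dims, rank) {
  list(A = matrix(stats::rnorm(dims[1] * rank), dims[1], rank),
       B = matrix(stats::rnorm(dims[2] * rank), dims[2], rank),
       C = matrix(stats::rnorm(dims[3] * rank), dims[3], rank))
}

svd_init <- function(X1, X2, X3, dims, rank) {
  lead <- function(M, n, r) {
    u <- svd(M, nu = min(r, min(dim(M))))$u
    if (ncol(u) < r) {
      u <- cbind(u, matrix(stats::rnorm(n * (r - ncol(u))), n))
    }
    u
  }
  list(A = lead(X1, dims[1], rank), B = lead(X2, dims[2], rank),
       C = lead(X3, dims[3], rank))
}

#' CP/PARAFAC decomposition by alternating least squares
#'
#' Fits the unconstrained rank-`rank` trilinear model to a three-way
#' spectra tensor. Each mode is updated by the exact least-squares
#' solution of its Khatri-Rao normal equations (with a tiny ridge for
#' conditioning under collinear concentration loadings); the relative
#' fit is non-increasing across sweeps. The best of `n_restarts`
#' independent initializations is returned, with the matched spectral
#' congruence between the two best restarts reported as a stability
#' diagnostic (low values signal a degenerate solution).
#'
#' Conventions: concentration loadings `B` and `C` have unit Euclidean
#' norm with the maximum-magnitude entry of each column positive; all
#' magnitude and remaining sign is carried by the spectral loadings
#' `A`, so factor spectra are directly comparable to measured component
#' and derivative spectra.
#'
#' @param x A [spectra_grid] or a numeric 3-way array
#'   (wavenumber x c1 x c2).
#' @param rank Number of factors (`>= 1`).
#' @param seed Integer; restart `k` uses `seed + k - 1`.
#' @param n_restarts Number of independent initializations.
#' @param max_iter Maximum ALS sweeps per restart.
#' @param tol Convergence threshold on the change of relative error.
#' @param init `"random"` (standard normal) or `"svd"` (leading
#'   singular vectors of the mode unfoldings; only the first restart
#'   uses it, the rest remain random).
#' @param ridge Ridge added to the normal equations.
#' @return A `cp_model` with loadings `A` (P x R, spectral), `B`
#'   (I x R), `C` (J x R), `rel_error`, iteration diagnostics and
#'   `restart_congruence`.
#' @export
cp_als <- function(x, rank, seed = 1L, n_restarts = 10L,
                   max_iter = 2000L, tol = 1e-10,
                   init = c("random", "svd"), ridge = 1e-12) {
  init <- match.arg(init)
  wavenumbers <- NULL
  if (inherits(x, "spectra_grid")) {
    wavenumbers <- x$wavenumbers
    x <- x$tensor
  }
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop_ternafac("x must be a 3-way array or spectra_grid")
  }
  if (anyNA(x) || any(!is.finite(x))) stop_ternafac("tensor has ",
                                                    "non-finite values")
  if (rank < 1L) stop_ternafac("rank must be >= 1")
  dims <- dim(x)
  if (min(dims[2], dims[3]) < 2L) {
    stop_ternafac("both concentration modes need at least 2 levels")
  }
  normX <- sqrt(sum(x^2))
  if (normX == 0) stop_ternafac("all-zero tensor")
  X1 <- matrix(x, dims[1], dims[2] * dims[3])
  X2 <- matrix(aperm(x, c(2, 1, 3)), dims[2], dims[1] * dims[3])
  X3 <- matrix(aperm(x, c(3, 1, 2)), dims[3], dims[1] * dims[2])

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  runs <- vector("list", n_restarts)
  for (k in seq_len(n_restarts)) {
    set.seed(as.integer(seed) + k - 1L)
    ini <- if (init == "svd" && k == 1L) {
      svd_init(X1, X2, X3, dims, rank)
    } else {
      random_init(dims, rank)
    }
    runs[[k]] <- als_single(X1, X2, X3, dims, rank, ini, max_iter, tol,
                            ridge, normX)
  }
  errs <- vapply(runs, `[[`, 0, "rel_error")
  ord <- order(errs)
  best <- runs[[ord[1]]]
  restart_congruence <- NA_real_
  if (n_restarts >= 2L) {
    second <- runs[[ord[2]]]
    m <- match_factors(best$A, second$A)
    restart_congruence <- min(m$congruence)
  }
  conv <- apply_conventions(best$A, best$B, best$C)
  new_cp_model(rank = rank, wavenumbers = wavenumbers,
               A = conv$A, B = conv$B, C = conv$C,
               rel_error = best$rel_error,
               n_iterations = best$n_iterations,
               converged = best$converged,
               restart_congruence = restart_congruence,
               rel_error_trace = best$rel_error_trace)
}

#' Reconstruct the fitted tensor of a CP model
#' @param model A `cp_model`.
#' @return Numeric 3-way array `P x I x J`.
#' @export
cp_reconstruct <- function(model) {
  stopifnot(inherits(model, "cp_model"))
  P <- nrow(model$A); I <- nrow(model$B); J <- nrow(model$C)
  array(model$A %*% t(khatri_rao(model$C, model$B)), dim = c(P, I, J))
}

#' Pairwise Tucker congruence between two loading matrices
#'
#' Entry `(r, s)` is the uncentered cosine between column `r` of `m1`
#' and column `s` of `m2`; with `m2 = m1` the off-diagonal entries are
#' the redundancy diagnostic used by [select_rank()].
#'
#' @param m1,m2 Numeric matrices with equal row counts; no zero-norm
#'   columns.
#' @return A `ncol(m1) x ncol(m2)` congruence matrix.
#' @export
factor_congruence <- function(m1, m2 = m1) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (nrow(m1) != nrow(m2)) stop_ternafac("row count mismatch")
  n1 <- sqrt(colSums(m1^2)); n2 <- sqrt(colSums(m2^2))
  if (any(n1 == 0) || any(n2 == 0)) stop_ternafac("zero-norm column")
  crossprod(m1, m2) / outer(n1, n2)
}

# like factor_congruence, but a collapsed (zero-norm) factor scores 0
# against everything instead of erroring; used by the matching and
# redundancy diagnostics where collapsed factors are expected on
# rank-deficient data
congruence_safe <- function(m1, m2 = m1) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  n1 <- sqrt(colSums(m1^2)); n2 <- sqrt(colSums(m2^2))
  out <- crossprod(m1, m2) /
    outer(pmax(n1, .Machine$double.xmin), pmax(n2, .Machine$double.xmin))
  out[n1 == 0, ] <- 0
  out[, n2 == 0] <- 0
  out
}

# light boxcar smoothing of spectral loadings before shape comparison:
# mimics visual shape judgement, which ignores point-to-point noise;
# the window (5 samples ~ 10 cm^-1 at 2 cm^-1 spacing) stays well
# below vibrational band widths
smooth_loading <- function(a, width = 5L) {
  f <- as.numeric(stats::filter(a, rep(1 / width, width), sides = 2))
  f[is.na(f)] <- a[is.na(f)]
  f
}

# lag-1 autocorrelation of a spectral loading: near 1 for band-like
# (smooth) shapes, near 0 for white noise; collapsed columns score 0
spectral_smoothness <- function(a) {
  ss <- sum(a^2)
  if (ss == 0) return(0)
  sum(a[-1] * a[-length(a)]) / ss
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    out <- rbind(out, cbind(k, sub + (sub >= k)))
  }
  out
}

#' Match estimated factors to reference factors
#'
#' Finds the column permutation of `est` that best matches `ref` by
#' absolute Tucker congruence (exhaustive search over permutations;
#' CP factor order and sign are indeterminate). Used to compare fitted
#' spectral loadings against planted ground-truth factors and between
#' restarts.
#'
#' @param est,ref Loading matrices with the same dimensions.
#' @return A list: `perm` (est column for each ref column),
#'   `congruence` (absolute matched congruence per reference factor).
#' @export
match_factors <- function(est, ref) {
  est <- as.matrix(est); ref <- as.matrix(ref)
  if (!all(dim(est) == dim(ref))) stop_ternafac("dimension mismatch")
  R <- ncol(ref)
  cg <- abs(congruence_safe(est, ref))   # est x ref
  perms <- permutations(R)
  best <- NULL; best_sum <- -Inf
  for (k in seq_len(nrow(perms))) {
    p <- perms[k, ]
    s <- sum(cg[cbind(p, seq_len(R))])
    if (s > best_sum) { best_sum <- s; best <- p }
  }
  list(perm = best, congruence = cg[cbind(best, seq_len(R))])
}

#' Incremental rank selection by factor redundancy and fit plateau
#'
#' Automates the step-up procedure for choosing the number of CP
#' factors: fit `r_min` factors, then `r_min + 1`, and so on, stopping
#' as soon as the larger model adds nothing new. "Nothing new" fires
#' when either (a) two spectral loadings within the larger model are
#' nearly the same shape (off-diagonal absolute congruence at or above
#' `redundancy_threshold` -- redundancy means the optimum was the
#' previous step), or (b) the relative-error improvement falls below
#' `fit_gain_threshold`. The scan keeps every fitted model so the
#' shapes can also be inspected visually.
#'
#' The minimum of two factors reflects what an isolated series must
#' contain: the unaffected component and the component affected by the
#' change of its own concentration; later factors carry interaction
#' information.
#'
#' @param x A [spectra_grid] or 3-way array.
#' @param r_min,r_max Scan range (`r_min >= 2`).
#' @param redundancy_threshold Absolute spectral congruence above which
#'   two factors count as duplicates.
#' @param fit_gain_threshold Minimum decrease in relative error that
#'   justifies an extra factor.
#' @param triple_congruence_threshold Absolute three-mode product
#'   congruence (spectral x both concentration modes) above which two
#'   factors count as one split or degenerate factor. Pairs that agree
#'   this strongly in *every* mode are the classic two-factor
#'   degeneracy of PARAFAC; the classical flag value is 0.85.
#' @param smoothness_threshold Minimum lag-1 autocorrelation of a
#'   factor's spectral loading for it to count as carrying spectral
#'   features. Real vibrational bands are much wider than the
#'   sampling step, so their loadings are smooth (autocorrelation
#'   near 1), while a factor fitted to detector noise is white
#'   (near 0); a model containing such a factor adds no spectral
#'   features and stops the scan. Set to `-Inf` to disable.
#' @param references,own_mode Optional: reference spectra and the
#'   series' own concentration mode, passed to [resolve_degeneracy()].
#'   When given (and `x` is a [spectra_grid]), every scanned model is
#'   canonicalized before the shape-based stopping rules are applied;
#'   without canonicalization, rotationally ambiguous factor groups
#'   can masquerade as redundant (or hide real redundancy).
#' @param seed,... Passed to [cp_als()].
#' @return An object of class `rank_scan`: `models` (one `cp_model`
#'   per scanned rank, canonicalized when references are given),
#'   `chosen_rank`, `stopping_reason` (one of `"redundancy"`,
#'   `"noise_factor"`, `"fit_plateau"`, `"r_max_reached"`), and
#'   `rel_errors`.
#' @export
select_rank <- function(x, r_min = 2L, r_max = 6L,
                        redundancy_threshold = 0.98,
                        fit_gain_threshold = 1e-3,
                        triple_congruence_threshold = 0.85,
                        smoothness_threshold = 0.5,
                        references = NULL, own_mode = NULL,
                        seed = 1L, ...) {
  if (r_max < r_min) stop_ternafac("r_max must be >= r_min")
  if (r_min < 2L) stop_ternafac("r_min must be >= 2 (an isolated ",
                                "series carries at least the pure and ",
                                "the concentration-change factor)")
  b_levels <- if (inherits(x, "spectra_grid")) x$c1_levels
  c_levels <- if (inherits(x, "spectra_grid")) x$c2_levels
  models <- list()
  chosen <- NULL; reason <- "r_max_reached"
  for (R in seq(r_min, r_max)) {
    m <- cp_als(x, rank = R, seed = seed, ...)
    if (!is.null(references)) {
      m <- resolve_degeneracy(m, references, own_mode = own_mode,
                              b_levels = b_levels, c_levels = c_levels)
    }
    models[[as.character(R)]] <- m
    if (R > r_min) {
      cg <- abs(congruence_safe(apply(m$A, 2, smooth_loading)))
      diag(cg) <- 0
      prev <- models[[as.character(R - 1L)]]
      cg3 <- cg * abs(congruence_safe(m$B)) * abs(congruence_safe(m$C))
      if (max(cg) >= redundancy_threshold ||
          max(cg3) >= triple_congruence_threshold) {
        chosen <- R - 1L; reason <- "redundancy"; break
      }
      smooth <- apply(m$A, 2, spectral_smoothness)
      if (any(smooth < smoothness_threshold)) {
        chosen <- R - 1L; reason <- "noise_factor"; break
      }
      if (prev$rel_error - m$rel_error < fit_gain_threshold) {
        chosen <- R - 1L; reason <- "fit_plateau"; break
      }
    }
  }
  if (is.null(chosen)) chosen <- r_max
  structure(list(models = models, chosen_rank = chosen,
                 stopping_reason = reason,
                 rel_errors = vapply(models, `[[`, 0, "rel_error")),
            class = "rank_scan")
}

#' @export
print.rank_scan <- function(x, ...) {
  cat(sprintf("Rank scan: chose %d factors (%s)\n", x$chosen_rank,
              x$stopping_reason))
  for (nm in names(x$models)) {
    cat(sprintf("  R = %s: rel_error = %.4g\n", nm,
                x$models[[nm]]$rel_error))
  }
  invisible(x)
}

#' Classify CP factors as pure, concentration-change or interaction
#'
#' Labels each factor of a CP model by comparing its spectral loading
#' (absolute Tucker congruence) against reference spectra: the pure
#' per-molar component spectra and the solutes' derivative spectra.
#' A factor matching a pure component is `pure_component`; one matching
#' a derivative spectrum is the `concentration_change` factor; anything
#' matching neither is a `candidate_interaction` -- the factors that
#' carry the information on solute-solute interactions. Because both
#' isolated series can carry the same differential information, the
#' comparison is made against the references of *all* solution
#' components, not only the main component of the series: pass lists.
#'
#' @param model A `cp_model`.
#' @param pure_component A [component_spectrum] or list of them.
#' @param deriv A `derivative_spectrum` or list of them (zero-norm
#'   derivative spectra are skipped).
#' @param threshold Absolute congruence at or above which a reference
#'   claims a factor; ties go to the larger congruence.
#' @return A data frame with one row per factor: `factor`, `label`,
#'   `congruence_pure`, `congruence_derivative`, `matched_reference`.
#' @export
classify_factors <- function(model, pure_component, deriv,
                             threshold = 0.95) {
  stopifnot(inherits(model, "cp_model"))
  pures <- if (inherits(pure_component, "component_spectrum")) {
    list(pure_component)
  } else pure_component
  derivs <- if (inherits(deriv, "derivative_spectrum")) {
    list(deriv)
  } else deriv
  R <- model$rank
  lab <- character(R); cgp <- numeric(R); cgd <- numeric(R)
  ref <- character(R)
  for (r in seq_len(R)) {
    a <- model$A[, r]
    best_p <- 0; best_p_name <- NA_character_
    for (p in pures) {
      if (max(abs(p$epsilon)) == 0) next
      v <- abs(tucker_congruence(a, p$epsilon))
      if (v > best_p) { best_p <- v; best_p_name <- p$component_name }
    }
    best_d <- 0; best_d_name <- NA_character_
    for (d in derivs) {
      if (max(abs(d$d_molar_absorbance)) == 0) next
      v <- abs(tucker_congruence(a, d$d_molar_absorbance))
      if (v > best_d) {
        best_d <- v
        best_d_name <- paste0("d/dc ", d$solute_name)
      }
    }
    cgp[r] <- best_p; cgd[r] <- best_d
    if (best_p >= threshold && best_p >= best_d) {
      lab[r] <- "pure_component"; ref[r] <- best_p_name
    } else if (best_d >= threshold) {
      lab[r] <- "concentration_change"; ref[r] <- best_d_name
    } else {
      lab[r] <- "candidate_interaction"; ref[r] <- NA_character_
    }
  }
  data.frame(factor = seq_len(R), label = lab,
             congruence_pure = cgp, congruence_derivative = cgd,
             matched_reference = ref)
}

# ---- rotational-degeneracy resolution ------------------------------------

# maximal groups of factor indices whose columns of M are mutually
# (anti)parallel within tol
parallel_groups <- function(M, tol) {
  cg <- abs(congruence_safe(M))
  R <- ncol(M)
  assigned <- rep(FALSE, R)
  groups <- list()
  for (r in seq_len(R)) {
    if (assigned[r]) next
    grp <- which(!assigned & cg[r, ] >= tol)
    grp <- union(r, grp)
    if (length(grp) >= 2L) {
      assigned[grp] <- TRUE
      groups[[length(groups) + 1L]] <- grp
    }
  }
  groups
}

unit <- function(v) v / sqrt(sum(v^2))

# choose up to m rotation targets among the reference spectra by how
# completely they project into the column space spanned by Q
pick_targets <- function(Q, refs, m, min_quality) {
  projs <- lapply(refs, function(v) drop(Q %*% crossprod(Q, v)))
  quality <- vapply(seq_along(refs), function(i) {
    sqrt(sum(projs[[i]]^2)) / sqrt(sum(refs[[i]]^2))
  }, 0)
  targets <- list()
  for (i in order(quality, decreasing = TRUE)) {
    if (quality[i] < min_quality) break
    p <- projs[[i]]
    dup <- any(vapply(targets, function(t) {
      abs(sum(unit(t) * unit(p))) > 0.99
    }, TRUE))
    if (!dup) targets[[length(targets) + 1L]] <- p
    if (length(targets) == m) break
  }
  targets
}

# rotate a degenerate group towards reference spectra; the
# compensating mode absorbs the inverse mixing
rotate_group_spectral <- function(Ag, Bcg, refs, min_quality) {
  m <- ncol(Ag)
  qrA <- qr(Ag)
  if (qrA$rank < m) return(NULL)           # collapsed factor: leave
  Q <- qr.Q(qrA)[, seq_len(m), drop = FALSE]
  targets <- pick_targets(Q, refs, m, min_quality)
  if (!length(targets)) return(NULL)       # nothing to aim at: leave
  Tg <- do.call(cbind, targets)
  if (ncol(Tg) < m) {
    # fill with the orthogonal complement of the targets inside the span
    qq <- qr.Q(qr(cbind(Tg, Q)))[, seq_len(m), drop = FALSE]
    Tg <- cbind(Tg, qq[, (ncol(Tg) + 1L):m, drop = FALSE])
  }
  Tmix <- qr.solve(Ag, Tg)
  if (abs(det(Tmix)) < 1e-12) return(NULL)
  list(A = Tg, Bc = Bcg %*% t(solve(Tmix)))
}

# structural canonicalization of an isolated-series model: split the
# fitted tensor into the part constant along the other solute's axis
# (slab at its zero level) and the part vanishing there (slab
# differences), decompose each, and re-solve the remaining mode
structural_canonicalize <- function(model, own_mode, other_levels,
                                    refs, min_quality,
                                    sv_rel = 0.1, sv_abs = 0.01,
                                    seed = 101L) {
  X <- cp_reconstruct(model)
  dims <- dim(X); R <- model$rank
  j0 <- which(other_levels == 0)
  if (length(j0) != 1L) stop_ternafac("no zero level on the other axis")
  if (own_mode == "B") {
    M0 <- X[, , j0]
    Z <- sweep(X[, , -j0, drop = FALSE], c(1, 2), M0, "-")
  } else {
    M0 <- X[, j0, ]
    Z <- sweep(X[, -j0, , drop = FALSE], c(1, 3), M0, "-")
  }
  normX <- sqrt(sum(X^2))
  sv <- svd(matrix(Z, dims[1]), nu = 0, nv = 0)$d
  nz <- sum(sv > pmax(sv_rel * sv[1], sv_abs * normX))
  nz <- min(nz, R - 1L)
  Az <- NULL; Lz <- NULL
  if (nz > 0L) {
    if (min(dim(Z)[2:3]) < 2L) stop_ternafac("degenerate slab split")
    fz <- cp_als(Z, rank = nz, seed = seed, n_restarts = 4L,
                 max_iter = 1000L, tol = 1e-12)
    Az <- fz$A
    Lz <- if (own_mode == "B") fz$B else fz$C   # own-axis loadings
  }
  nc <- R - nz
  Ac <- NULL; Lc <- NULL
  if (nc > 0L) {
    sm <- svd(M0)
    Q <- sm$u[, seq_len(min(nc, ncol(sm$u))), drop = FALSE]
    targets <- pick_targets(Q, refs, nc, min_quality)
    Tg <- if (length(targets)) do.call(cbind, targets) else NULL
    if (is.null(Tg) || ncol(Tg) < nc) {
      have <- if (is.null(Tg)) 0L else ncol(Tg)
      qq <- qr.Q(qr(cbind(Tg, Q)))[, seq_len(nc), drop = FALSE]
      Tg <- cbind(Tg, qq[, (have + 1L):nc, drop = FALSE])
    }
    Ac <- Tg
    Lc <- t(qr.solve(Ac, M0))               # own-axis loadings
  }
  Anew <- cbind(Ac, Az)
  if (qr(Anew)$rank < R) stop_ternafac("canonical spectral loadings ",
                                       "not independent")
  if (own_mode == "B") {
    Bnew <- cbind(Lc, Lz)
    X3 <- matrix(aperm(X, c(3, 1, 2)), dims[3], dims[1] * dims[2])
    Cnew <- t(qr.solve(khatri_rao(Bnew, Anew), t(X3)))
  } else {
    Cnew <- cbind(Lc, Lz)
    X2 <- matrix(aperm(X, c(2, 1, 3)), dims[2], dims[1] * dims[3])
    Bnew <- t(qr.solve(khatri_rao(Cnew, Anew), t(X2)))
  }
  conv <- apply_conventions(Anew, Bnew, Cnew)
  model$A <- conv$A; model$B <- conv$B; model$C <- conv$C
  model
}

#' Resolve rotational ambiguity of degenerate CP factors
#'
#' The trilinear model of an isolated series is often not fully
#' unique: whenever two factors share (anti)parallel loadings in one
#' concentration mode, the pair can be mixed by any invertible matrix
#' -- with the other mode absorbing the inverse -- without changing
#' the reconstruction. In a non-interacting isolated series *every*
#' factor is constant along the other solute's axis, so the pure and
#' concentration-change factors emerge as arbitrary mixtures. Factor
#' identity is then established the way the method identifies factors
#' in general, by comparison with known structure, leaving the fitted
#' tensor unchanged:
#'
#' * When the series' own concentration mode is known (`own_mode`) and
#'   the other axis includes a zero level, the fitted tensor is split
#'   exactly into the part constant along the other axis (its zero
#'   slab: pure component and own-concentration factors) and the part
#'   vanishing there (slab differences: interaction factors and
#'   duplicated changes of the other solute). Each part is decomposed
#'   separately -- the vanishing part is trilinear-identifiable on its
#'   own, the constant part is rotated onto the best-matching
#'   reference spectra -- and the remaining mode is re-solved by least
#'   squares.
#' * Otherwise, groups of factors with parallel concentration loadings
#'   are detected pairwise and their spectral subspaces rotated onto
#'   the best-matching reference spectra (pure components, derivative
#'   spectra); columns with no matching reference take the orthogonal
#'   complement within the subspace.
#'
#' @param model A `cp_model`.
#' @param references List of reference spectra on the model's
#'   wavenumber axis: numeric vectors, [component_spectrum]s or
#'   `derivative_spectrum`s (zero-norm references are skipped).
#' @param own_mode `"B"` if the series' main component varies along
#'   the first concentration mode (an NMA-isolated series), `"C"` for
#'   the second (an osmolyte-isolated series), or `NULL` if unknown
#'   (pairwise strategy only).
#' @param b_levels,c_levels Concentration levels of the two modes
#'   (needed to locate the other axis' zero level).
#' @param parallel_tol Absolute congruence above which two
#'   concentration loadings count as parallel (pairwise strategy).
#' @param min_quality Minimum fraction of a reference's norm that must
#'   project into the relevant subspace for it to be used as a target.
#' @return A `cp_model` with the same fit and possibly rotated factors.
#' @export
resolve_degeneracy <- function(model, references, own_mode = NULL,
                               b_levels = NULL, c_levels = NULL,
                               parallel_tol = 0.999,
                               min_quality = 0.9) {
  stopifnot(inherits(model, "cp_model"))
  refs <- Filter(function(v) is.numeric(v) && sum(v^2) > 0,
                 lapply(references, function(r) {
                   if (is.numeric(r)) r
                   else if (!is.null(r$epsilon)) r$epsilon
                   else if (!is.null(r$d_molar_absorbance)) {
                     r$d_molar_absorbance
                   } else NULL
                 }))
  if (model$rank < 2L) return(model)
  if (!is.null(own_mode)) {
    own_mode <- match.arg(own_mode, c("B", "C"))
    other_levels <- if (own_mode == "B") c_levels else b_levels
    if (!is.null(other_levels)) {
      out <- tryCatch(
        structural_canonicalize(model, own_mode, other_levels, refs,
                                min_quality),
        ternafac_error = function(e) NULL)
      if (!is.null(out)) return(out)
    }
  }
  # pairwise fallback: rotate parallel-loading groups onto references.
  # Groups from both modes are ranked by how tightly parallel they are
  # (the rotation is exact only where the shared loadings coincide) and
  # each factor is rotated at most once.
  if (!length(refs)) return(model)
  A <- model$A; B <- model$B; C <- model$C
  cand <- list()
  for (mode in c("B", "C")) {
    M <- if (mode == "B") B else C
    cg <- abs(congruence_safe(M))
    for (grp in parallel_groups(M, parallel_tol)) {
      tightness <- min(cg[grp, grp])
      cand[[length(cand) + 1L]] <- list(mode = mode, grp = grp,
                                        tightness = tightness)
    }
  }
  if (length(cand)) {
    ord <- order(vapply(cand, `[[`, 0, "tightness"), decreasing = TRUE)
    used <- integer(0)
    for (k in ord) {
      grp <- cand[[k]]$grp
      if (length(intersect(grp, used))) next
      mode <- cand[[k]]$mode
      other <- if (mode == "B") C else B
      rot <- rotate_group_spectral(A[, grp, drop = FALSE],
                                   other[, grp, drop = FALSE],
                                   refs, min_quality)
      if (is.null(rot)) next
      A[, grp] <- rot$A
      if (mode == "B") C[, grp] <- rot$Bc else B[, grp] <- rot$Bc
      used <- c(used, grp)
    }
  }
  conv <- apply_conventions(A, B, C)
  model$A <- conv$A; model$B <- conv$B; model$C <- conv$C
  model
}
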