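# Derivative spectra: the per-wavenumber derivative of molar absorbance
# with respect to a solute's concentration over its binary (solute +
# water) series. A purely Beer-Lambert series has constant molar
# absorbance, hence a zero derivative; band shifts or self-association
# make the derivative spectrum-like, and it identifies the
# concentration-change factor among the CP factors.

#' Concentration derivative of molar absorbance over a binary series
#'
#' Takes a water-subtracted binary series (one solute + water), forms
#' the molar absorbance `a(v, c) = A(v, c) / c` at each concentration
#' `c > 0`, and fits, per wavenumber, the ordinary least-squares slope
#' of `a` versus `c` across the whole series. The slope is exact for a
#' molar absorbance linear in `c` (the self-association model) and
#' noise-robust because every concentration contributes. Points with
#' `c = 0` (molar absorbance undefined) are excluded with a message.
#'
#' @param series A water-subtracted [scattered_spectra] binary series;
#'   the other solute's concentration must be zero throughout, and at
#'   least 3 distinct concentrations must be strictly positive.
#' @param solute `"nma"` or `"osmolyte"`.
#' @return An object of class `derivative_spectrum` with fields
#'   `wavenumbers`, `d_molar_absorbance` (AU dm^6 mol^-2),
#'   `solute_name` and `concentration_range`.
#' @export
derivative_spectrum <- function(series, solute = c("nma", "osmolyte")) {
  solute <- match.arg(solute)
  stopifnot(inherits(series, "scattered_spectra"))
  conc <- series$concentrations
  cc <- if (solute == "nma") conc$c_nma else conc$c_osm
  other <- if (solute == "nma") conc$c_osm else conc$c_nma
  if (any(other != 0)) {
    stop_ternafac("series must be binary: the other solute must be ",
                  "absent everywhere")
  }
  zero <- cc == 0
  if (any(zero)) {
    message(sum(zero), " spectrum/spectra at c = 0 excluded from the ",
            "derivative (molar absorbance undefined at zero ",
            "concentration)")
  }
  cc_pos <- cc[!zero]
  if (length(unique(cc_pos)) < 3L) {
    stop_ternafac("need at least 3 distinct positive concentrations")
  }
  A <- series$absorbance[, !zero, drop = FALSE]
  a <- sweep(A, 2, cc_pos, "/")          # molar absorbance, P x n
  # OLS slope of a vs c, per wavenumber (vectorised over rows)
  cbar <- mean(cc_pos)
  dc <- cc_pos - cbar
  slope <- drop(a %*% dc) / sum(dc^2)
  structure(list(wavenumbers = series$wavenumbers,
                 d_molar_absorbance = slope,
                 solute_name = solute,
                 concentration_range = range(cc_pos)),
            class = "derivative_spectrum")
}

#' @export
print.derivative_spectrum <- function(x, ...) {
  cat(sprintf(
    "Derivative spectrum of %s over c in [%g, %g] M, max |d| = %.4g\n",
    x$solute_name, x$concentration_range[1], x$concentration_range[2],
    max(abs(x$d_molar_absorbance))))
  invisible(x)
}

#' Tucker congruence between two loading vectors
#'
#' The uncentered cosine `sum(x*y) / sqrt(sum(x^2) * sum(y^2))`, the
#' standard factor-matching coefficient. Values near +/-1 indicate the
#' same spectral shape up to scale and sign (CP factors are
#' sign-indeterminate, so matching uses the absolute value).
#'
#' @param x,y Numeric vectors of equal length; neither may have zero
#'   norm.
#' @return Congruence in `[-1, 1]`.
#' @export
tucker_congruence <- function(x, y) {
  if (length(x) != length(y)) stop_ternafac("length mismatch")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop_ternafac("zero-norm vector")
  sum(x * y) / (nx * ny)
}

#' Match a CP factor spectrum against a derivative spectrum
#'
#' Computes the Tucker congruence between a factor's spectral loading
#' and a solute's derivative spectrum. `|congruence|` near 1 flags the
#' factor as the concentration-change factor, which must not be
#' mistaken for an interaction factor.
#'
#' @param factor_spectrum Numeric vector (a column of a CP model's
#'   spectral loadings) or an object with `wavenumbers`/values.
#' @param derivative A `derivative_spectrum`.
#' @return Congruence in `[-1, 1]`.
#' @export
match_factor_to_derivative <- function(factor_spectrum, derivative) {
  stopifnot(inherits(derivative, "derivative_spectrum"))
  v <- if (is.numeric(factor_spectrum)) {
    factor_spectrum
  } else if (!is.null(factor_spectrum$epsilon)) {
    if (!common_axis_check(factor_spectrum, derivative)) {
      stop_ternafac("factor and derivative axes differ")
    }
    factor_spectrum$epsilon
  } else {
    stop_ternafac("factor_spectrum must be numeric or a ",
                  "component_spectrum")
  }
  tucker_congruence(v, derivative$d_molar_absorbance)
}
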