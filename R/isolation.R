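# Sequential removal of known contributions from the interpolated grid:
# water first, then one solute, yielding the two "isolated" three-way
# series that feed the trilinear decomposition. Negative residual bands
# are meaningful (shifts, width changes) and are never clipped.

#' Volume-additive water concentration model
#'
#' Water molarity in a ternary solution is modelled by volume
#' additivity: `c_w = c_w_pure * (1 - c1*vbar_nma - c2*vbar_osm)`, where
#' the partial molar volumes are in dm^3 mol^-1. The defaults set both
#' partial molar volumes to zero -- the explicit constant-water
#' approximation -- so that any dilution correction is a deliberate,
#' visible choice rather than a guess.
#'
#' @param pure_water_molarity Molarity of pure water, mol dm^-3
#'   (55.345 at 25 C).
#' @param vbar_nma,vbar_osm Partial molar volumes of the two solutes,
#'   dm^3 mol^-1.
#' @return An object of class `water_model`.
#' @export
water_model <- function(pure_water_molarity = 55.345,
                        vbar_nma = 0, vbar_osm = 0) {
  stopifnot(pure_water_molarity > 0, vbar_nma >= 0, vbar_osm >= 0)
  structure(list(pure_water_molarity = pure_water_molarity,
                 vbar_nma = vbar_nma, vbar_osm = vbar_osm),
            class = "water_model")
}

#' Water molarity at a given solution composition
#'
#' @param c1,c2 Solute molarities, mol dm^-3 (vectorised; recycled to a
#'   common length).
#' @param model A [water_model].
#' @return Water molarity (mol dm^-3), same length as the inputs. A
#'   nonphysical composition (computed water concentration `<= 0`) is an
#'   error naming the offending composition, never a clamped value.
#' @export
water_concentration <- function(c1, c2, model = water_model()) {
  stopifnot(inherits(model, "water_model"))
  if (any(c1 < 0) || any(c2 < 0)) {
    stop_ternafac("concentrations must be non-negative")
  }
  cw <- model$pure_water_molarity *
    (1 - c1 * model$vbar_nma - c2 * model$vbar_osm)
  bad <- which(cw <= 0)
  if (length(bad)) {
    stop_ternafac(sprintf(
      "nonphysical water concentration (%.4g) at c1 = %g, c2 = %g",
      cw[bad[1]], rep_len(c1, length(cw))[bad[1]],
      rep_len(c2, length(cw))[bad[1]]))
  }
  cw
}

#' Subtract the water contribution from a grid or series
#'
#' Removes `(c_w / c_w_pure) * A_water(v)` from every spectrum, where
#' `c_w` comes from the volume-additive [water_model]. This is the first
#' subtraction stage; the pure-water node of an ideal grid maps to the
#' zero spectrum.
#'
#' @param x A [spectra_grid] or [scattered_spectra].
#' @param water_ref Pure-water reference [ftir_spectrum] on the same
#'   wavenumber axis.
#' @param model A [water_model].
#' @return An object of the same class as `x` with water removed.
#' @export
subtract_water <- function(x, water_ref, model = water_model()) {
  stopifnot(inherits(water_ref, "ftir_spectrum"))
  require_common_axis(x, water_ref, what = "grid and water reference")
  if (inherits(x, "spectra_grid")) {
    cw <- outer(x$c1_levels, x$c2_levels,
                function(a, b) water_concentration(a, b, model))
    coeff <- cw / model$pure_water_molarity
    x$tensor <- x$tensor - outer(water_ref$absorbance, coeff)
    return(x)
  }
  if (inherits(x, "scattered_spectra")) {
    cw <- water_concentration(x$concentrations$c_nma,
                              x$concentrations$c_osm, model)
    x$absorbance <- x$absorbance -
      outer(water_ref$absorbance, cw / model$pure_water_molarity)
    return(x)
  }
  stop_ternafac("x must be a spectra_grid or scattered_spectra")
}

#' Estimate a solute's per-molar spectrum from its binary series
#'
#' Given spectra of binary solute-water solutions (the `c = 0` edge of
#' the design for the other solute), subtracts the water contribution
#' from each spectrum and fits, per wavenumber, the through-origin
#' least-squares slope of residual absorbance versus solute
#' concentration. The slope vector is the per-molar absorptivity
#' `epsilon(v)` used for the solute subtraction stage.
#'
#' @param binary_series A [scattered_spectra] in which the *other*
#'   solute's concentration is identically zero and at least 3 distinct
#'   nonzero concentrations of the target solute are present.
#' @param water_ref Pure-water reference [ftir_spectrum].
#' @param model A [water_model].
#' @param solute `"nma"` or `"osmolyte"`: which axis the series varies.
#' @return A [component_spectrum] for the solute.
#' @export
estimate_component_spectrum <- function(binary_series, water_ref,
                                        model = water_model(),
                                        solute = c("nma", "osmolyte")) {
  solute <- match.arg(solute)
  stopifnot(inherits(binary_series, "scattered_spectra"))
  conc <- binary_series$concentrations
  target <- if (solute == "nma") conc$c_nma else conc$c_osm
  other <- if (solute == "nma") conc$c_osm else conc$c_nma
  if (any(other != 0)) {
    stop_ternafac("binary series must have the other solute at zero ",
                  "concentration everywhere")
  }
  if (length(unique(target[target > 0])) < 3L) {
    stop_ternafac("need at least 3 distinct nonzero concentrations of ",
                  solute)
  }
  resid <- subtract_water(binary_series, water_ref, model)
  keep <- target > 0
  A <- resid$absorbance[, keep, drop = FALSE]
  cc <- target[keep]
  # through-origin LS per wavenumber: slope = (A %*% c) / sum(c^2)
  eps <- drop(A %*% cc) / sum(cc^2)
  if (max(abs(eps)) == 0) {
    warning("estimated component spectrum is identically zero ",
            "(IR-silent component?)")
  }
  component_spectrum(binary_series$wavenumbers, eps,
                     component_name = solute,
                     reference_concentration = max(cc))
}

#' Subtract one solute's contribution from a water-subtracted grid
#'
#' Removes `c_axis(i, j) * epsilon(v)` from every node, producing the
#' solute-isolated series: subtracting the NMA component leaves the
#' osmolyte-related signal and vice versa. Negative values (difference
#' bands from shifts or over-strict subtraction) are preserved -- they
#' carry the interaction information the decomposition looks for.
#'
#' @param grid A water-subtracted [spectra_grid].
#' @param component The solute's [component_spectrum].
#' @param axis `"nma"` or `"osmolyte"`: which concentration axis scales
#'   the subtraction. Must match `component$component_name`.
#' @return A [spectra_grid] devoid of that solute's contribution.
#' @export
subtract_solute <- function(grid, component,
                            axis = c("nma", "osmolyte")) {
  axis <- match.arg(axis)
  stopifnot(inherits(grid, "spectra_grid"),
            inherits(component, "component_spectrum"))
  require_common_axis(grid, component, what = "grid and component")
  if (component$component_name != axis) {
    stop_ternafac("component is '", component$component_name,
                  "' but axis is '", axis, "'")
  }
  I <- length(grid$c1_levels); J <- length(grid$c2_levels)
  cmat <- if (axis == "nma") {
    matrix(grid$c1_levels, I, J)
  } else {
    matrix(grid$c2_levels, I, J, byrow = TRUE)
  }
  grid$tensor <- grid$tensor - outer(component$epsilon, cmat)
  grid
}
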