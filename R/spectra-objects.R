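#' @keywords internal
"_PACKAGE"

# ---- shared validation helpers -------------------------------------------

stop_ternafac <- function(..., class = "ternafac_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_numeric_finite <- function(x, what) {
  if (!is.numeric(x)) stop_ternafac(what, " must be numeric")
  if (anyNA(x) || any(!is.finite(x))) {
    stop_ternafac(what, " contains non-finite values")
  }
  invisible(x)
}

check_strictly_monotone <- function(w, what = "wavenumbers") {
  d <- diff(w)
  if (length(w) < 2L || any(d <= 0)) {
    stop_ternafac(what, " must be strictly increasing")
  }
  invisible(w)
}

# Canonical wavenumber order is ascending; descending input is reversed
# together with its ordinate(s).
canonical_axis <- function(wavenumbers, ordinates) {
  check_numeric_finite(wavenumbers, "wavenumbers")
  if (length(wavenumbers) >= 2L && all(diff(wavenumbers) < 0)) {
    wavenumbers <- rev(wavenumbers)
    ordinates <- if (is.matrix(ordinates)) {
      ordinates[rev(seq_len(nrow(ordinates))), , drop = FALSE]
    } else {
      rev(ordinates)
    }
  }
  check_strictly_monotone(wavenumbers)
  list(wavenumbers = wavenumbers, ordinates = ordinates)
}

# ---- Spectrum -------------------------------------------------------------

#' Single absorbance spectrum of one solution
#'
#' A `ftir_spectrum` holds one absorbance trace together with the molar
#' composition of the solution it was measured on. Absorbance may be
#' negative: difference spectra produced by subtraction are first-class
#' objects and are never clipped anywhere in the package.
#'
#' @param wavenumbers Numeric vector, cm^-1. Strictly monotone; a
#'   descending axis is reversed (with the absorbance) on construction.
#' @param absorbance Numeric vector of absorbance values (AU), same length
#'   as `wavenumbers`.
#' @param c_nma,c_osm Molar concentrations (mol dm^-3) of the peptide
#'   model (N-methylacetamide) and the osmolyte; both `>= 0`.
#' @param label Free-text label.
#' @return An object of class `ftir_spectrum`.
#' @examples
#' s <- ftir_spectrum(seq(1300, 1700, by = 2),
#'                    rnorm(201, 0, 0.01), c_nma = 0.5, c_osm = 0)
#' s
#' @export
ftir_spectrum <- function(wavenumbers, absorbance, c_nma = 0, c_osm = 0,
                          label = "") {
  check_numeric_finite(absorbance, "absorbance")
  if (length(wavenumbers) != length(absorbance)) {
    stop_ternafac("wavenumbers and absorbance differ in length")
  }
  ax <- canonical_axis(wavenumbers, absorbance)
  if (!is.numeric(c_nma) || !is.numeric(c_osm) || c_nma < 0 || c_osm < 0) {
    stop_ternafac("concentrations must be non-negative numbers")
  }
  structure(list(wavenumbers = ax$wavenumbers, absorbance = ax$ordinates,
                 c_nma = as.numeric(c_nma), c_osm = as.numeric(c_osm),
                 label = as.character(label)),
            class = "ftir_spectrum")
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat(sprintf(
    "FTIR spectrum%s: %d points, %.1f-%.1f cm-1, c_nma = %g, c_osm = %g M\n",
    if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
    length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers),
    x$c_nma, x$c_osm))
  invisible(x)
}

# ---- ScatteredSpectraSet --------------------------------------------------

#' Spectra series at scattered concentration points
#'
#' A `scattered_spectra` object is a series of absorbance spectra sharing
#' one wavenumber axis, each labelled with a `(c_nma, c_osm)` composition.
#' The composition points need not be unique or evenly spaced -- this is
#' the container for an as-prepared concentration design, before
#' interpolation onto a regular grid.
#'
#' @param wavenumbers Shared wavenumber axis, cm^-1, strictly ascending
#'   (a descending axis is reversed along with the absorbance matrix).
#' @param absorbance Numeric matrix, `length(wavenumbers)` rows, one
#'   column per solution.
#' @param concentrations Data frame with numeric columns `c_nma` and
#'   `c_osm` (mol dm^-3), one row per solution; an optional `label`
#'   column names the solutions.
#' @param design_note Free-text description of the design.
#' @return An object of class `scattered_spectra`.
#' @export
scattered_spectra <- function(wavenumbers, absorbance, concentrations,
                              design_note = "") {
  if (!is.matrix(absorbance)) absorbance <- as.matrix(absorbance)
  check_numeric_finite(absorbance, "absorbance")
  if (nrow(absorbance) != length(wavenumbers)) {
    stop_ternafac("absorbance must have one row per wavenumber")
  }
  ax <- canonical_axis(wavenumbers, absorbance)
  if (!all(c("c_nma", "c_osm") %in% names(concentrations))) {
    stop_ternafac("concentrations needs columns c_nma and c_osm")
  }
  if (nrow(concentrations) != ncol(absorbance)) {
    stop_ternafac("one concentration row per spectrum required")
  }
  check_numeric_finite(concentrations$c_nma, "c_nma")
  check_numeric_finite(concentrations$c_osm, "c_osm")
  if (any(concentrations$c_nma < 0) || any(concentrations$c_osm < 0)) {
    stop_ternafac("concentrations must be non-negative")
  }
  if (is.null(concentrations$label)) {
    concentrations$label <- sprintf("sol%02d", seq_len(nrow(concentrations)))
  }
  concentrations <- as.data.frame(
    concentrations[c("c_nma", "c_osm", "label")])
  colnames(ax$ordinates) <- concentrations$label
  structure(list(wavenumbers = ax$wavenumbers, absorbance = ax$ordinates,
                 concentrations = concentrations,
                 design_note = as.character(design_note)),
            class = "scattered_spectra")
}

#' @export
print.scattered_spectra <- function(x, ...) {
  cat(sprintf(
    "Scattered FTIR series: %d spectra x %d wavenumbers (%.1f-%.1f cm-1)\n",
    ncol(x$absorbance), length(x$wavenumbers),
    min(x$wavenumbers), max(x$wavenumbers)))
  cat(sprintf("  c_nma in [%g, %g] M, c_osm in [%g, %g] M\n",
              min(x$concentrations$c_nma), max(x$concentrations$c_nma),
              min(x$concentrations$c_osm), max(x$concentrations$c_osm)))
  if (nzchar(x$design_note)) cat("  ", x$design_note, "\n", sep = "")
  invisible(x)
}

#' Number of spectra in a series
#' @param x A `scattered_spectra` or `spectra_grid` object.
#' @return Integer count of spectra.
#' @export
n_spectra <- function(x) {
  if (inherits(x, "scattered_spectra")) return(ncol(x$absorbance))
  if (inherits(x, "spectra_grid")) {
    return(length(x$c1_levels) * length(x$c2_levels))
  }
  stop_ternafac("no n_spectra method for class ", class(x)[1])
}

#' Extract one spectrum from a series
#' @param x A `scattered_spectra` object.
#' @param i Column index.
#' @return A `ftir_spectrum`.
#' @export
get_spectrum <- function(x, i) {
  stopifnot(inherits(x, "scattered_spectra"))
  ftir_spectrum(x$wavenumbers, x$absorbance[, i],
                c_nma = x$concentrations$c_nma[i],
                c_osm = x$concentrations$c_osm[i],
                label = x$concentrations$label[i])
}

#' Subset a scattered series by solution
#' @param x A `scattered_spectra` object.
#' @param keep Logical or integer index over solutions.
#' @return A `scattered_spectra` with the selected solutions.
#' @export
subset_spectra <- function(x, keep) {
  stopifnot(inherits(x, "scattered_spectra"))
  scattered_spectra(x$wavenumbers, x$absorbance[, keep, drop = FALSE],
                    x$concentrations[keep, , drop = FALSE],
                    design_note = x$design_note)
}

# ---- SpectraGrid ----------------------------------------------------------

#' Three-way spectra tensor on a regular concentration grid
#'
#' A `spectra_grid` is the three-way array at the heart of the trilinear
#' analysis: wavenumber x NMA concentration level x osmolyte
#' concentration level. It is produced by [interpolate_grid()] and
#' consumed by the subtraction and CP decomposition steps.
#'
#' @param wavenumbers Wavenumber axis, cm^-1, strictly ascending.
#' @param c1_levels,c2_levels Strictly increasing, non-negative
#'   concentration levels (mol dm^-3) of the NMA and osmolyte axes.
#' @param tensor Numeric array `P x I x J` of absorbance values with
#'   `P = length(wavenumbers)`, `I = length(c1_levels)`,
#'   `J = length(c2_levels)`.
#' @return An object of class `spectra_grid`.
#' @export
spectra_grid <- function(wavenumbers, c1_levels, c2_levels, tensor) {
  check_numeric_finite(wavenumbers, "wavenumbers")
  check_strictly_monotone(wavenumbers)
  for (nm in c("c1_levels", "c2_levels")) {
    lv <- get(nm)
    check_numeric_finite(lv, nm)
    if (any(lv < 0)) stop_ternafac(nm, " must be non-negative")
    if (length(lv) >= 2L) check_strictly_monotone(lv, nm)
  }
  check_numeric_finite(tensor, "tensor")
  if (!is.array(tensor) || length(dim(tensor)) != 3L ||
      !all(dim(tensor) == c(length(wavenumbers), length(c1_levels),
                            length(c2_levels)))) {
    stop_ternafac("tensor must be a P x I x J array matching the axes")
  }
  structure(list(wavenumbers = wavenumbers, c1_levels = c1_levels,
                 c2_levels = c2_levels, tensor = tensor),
            class = "spectra_grid")
}

#' @export
print.spectra_grid <- function(x, ...) {
  cat(sprintf(
    "Spectra grid: %d wavenumbers x %d NMA levels x %d osmolyte levels\n",
    length(x$wavenumbers), length(x$c1_levels), length(x$c2_levels)))
  cat(sprintf("  c_nma levels: %s\n  c_osm levels: %s\n",
              paste(signif(x$c1_levels, 4), collapse = ", "),
              paste(signif(x$c2_levels, 4), collapse = ", ")))
  invisible(x)
}

# Flatten a grid to a scattered set (column order: c2 outer, c1 inner).
grid_to_scattered <- function(grid) {
  P <- length(grid$wavenumbers)
  I <- length(grid$c1_levels); J <- length(grid$c2_levels)
  conc <- expand.grid(c_nma = grid$c1_levels, c_osm = grid$c2_levels,
                      KEEP.OUT.ATTRS = FALSE)
  conc$label <- sprintf("grid_n%g_o%g", conc$c_nma, conc$c_osm)
  scattered_spectra(grid$wavenumbers, matrix(grid$tensor, nrow = P),
                    conc, design_note = "flattened regular grid")
}

# ---- ComponentSpectrum ----------------------------------------------------

#' Per-molar absorptivity trace of one solution component
#'
#' Holds the spectral contribution of one component per unit molar
#' concentration: `epsilon(v)` in AU per mol dm^-3. Multiplying by the
#' component's concentration gives its additive Beer-Lambert
#' contribution to a solution spectrum.
#'
#' @param wavenumbers Wavenumber axis, cm^-1.
#' @param epsilon Per-molar absorptivity (AU per mol dm^-3), same length.
#' @param component_name One of `"water"`, `"nma"`, `"osmolyte"`.
#' @param reference_concentration Reference molarity (mol dm^-3); for
#'   water, the molarity of pure water used for scaling.
#' @return An object of class `component_spectrum`.
#' @export
component_spectrum <- function(wavenumbers, epsilon,
                               component_name = c("water", "nma", "osmolyte"),
                               reference_concentration = NA_real_) {
  component_name <- match.arg(component_name)
  check_numeric_finite(epsilon, "epsilon")
  if (length(wavenumbers) != length(epsilon)) {
    stop_ternafac("wavenumbers and epsilon differ in length")
  }
  ax <- canonical_axis(wavenumbers, epsilon)
  structure(list(wavenumbers = ax$wavenumbers, epsilon = ax$ordinates,
                 component_name = component_name,
                 reference_concentration = as.numeric(
                   reference_concentration)),
            class = "component_spectrum")
}

#' @export
print.component_spectrum <- function(x, ...) {
  cat(sprintf("Component spectrum '%s': %d points, max |epsilon| = %.4g\n",
              x$component_name, length(x$wavenumbers),
              max(abs(x$epsilon))))
  invisible(x)
}

# ---- axis comparison ------------------------------------------------------

#' Check that several objects share one wavenumber axis
#'
#' Predicate used at every module boundary: no resampling onto a common
#' axis is ever performed silently, so objects entering a joint
#' operation must agree to within `tol`.
#'
#' @param ... Two or more objects with a `wavenumbers` field
#'   (spectra, series, grids, component or derivative spectra).
#' @param tol Maximum allowed absolute axis difference, cm^-1.
#' @return `TRUE` if all axes are equal within `tol`, else `FALSE`.
#' @export
common_axis_check <- function(..., tol = 1e-9) {
  objs <- list(...)
  if (length(objs) < 2L) stop_ternafac("need at least two objects")
  axes <- lapply(objs, function(o) o$wavenumbers)
  ref <- axes[[1]]
  for (a in axes[-1]) {
    if (length(a) != length(ref) || max(abs(a - ref)) > tol) return(FALSE)
  }
  TRUE
}

require_common_axis <- function(..., what = "inputs") {
  if (!common_axis_check(...)) {
    stop_ternafac(what, " do not share a common wavenumber axis")
  }
  invisible(TRUE)
}
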