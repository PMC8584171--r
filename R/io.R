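# File I/O: wide CSV + JSON/YAML sidecar for spectra series, a minimal
# JCAMP-DX reader for single reference spectra, JSON for CP models.

read_sidecar <- function(sidecar_path) {
  if (!file.exists(sidecar_path)) {
    stop_ternafac("sidecar file not found: ", sidecar_path)
  }
  ext <- tolower(tools::file_ext(sidecar_path))
  meta <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(sidecar_path)
  } else {
    jsonlite::read_json(sidecar_path, simplifyVector = FALSE)
  }
  if (!is.list(meta) || is.null(names(meta))) {
    stop_ternafac("sidecar must map column names to {c_nma, c_osm}")
  }
  meta
}

#' Read a wide-CSV spectra series with a concentration sidecar
#'
#' The on-disk format is a UTF-8 CSV whose first column is the
#' wavenumber axis (cm^-1) and whose remaining columns are one solution
#' each, plus a JSON or YAML sidecar mapping every column name to its
#' composition: `{"colname": {"c_nma": x, "c_osm": y}}`. A descending
#' wavenumber axis is reversed on load; values are never smoothed,
#' baseline-corrected or otherwise altered.
#'
#' @param path CSV file path.
#' @param sidecar_path Sidecar path; defaults to `path` with its
#'   extension replaced by `.json`.
#' @return A [scattered_spectra] object.
#' @export
read_spectra_csv <- function(path,
                             sidecar_path = paste0(
                               tools::file_path_sans_ext(path), ".json")) {
  if (!file.exists(path)) stop_ternafac("file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (ncol(tab) < 2L) stop_ternafac("CSV needs a wavenumber column plus ",
                                    "at least one spectrum column")
  for (j in seq_along(tab)) {
    if (!is.numeric(tab[[j]])) {
      stop_ternafac("non-numeric values in column '", names(tab)[j], "'")
    }
    if (anyNA(tab[[j]])) {
      stop_ternafac("missing/ragged values in column '", names(tab)[j], "'")
    }
  }
  meta <- read_sidecar(sidecar_path)
  cols <- names(tab)[-1]
  missing_meta <- setdiff(cols, names(meta))
  if (length(missing_meta)) {
    stop_ternafac("sidecar has no concentrations for column '",
                  missing_meta[1], "'")
  }
  conc <- data.frame(
    c_nma = vapply(meta[cols], function(m) as.numeric(m$c_nma), 0),
    c_osm = vapply(meta[cols], function(m) as.numeric(m$c_osm), 0),
    label = cols)
  scattered_spectra(tab[[1]], as.matrix(tab[-1]), conc)
}

#' Write a spectra series or grid as wide CSV plus sidecar
#'
#' Values round-trip through [read_spectra_csv()] to within 1e-12; the
#' sidecar carries the exact compositions. A `spectra_grid` is flattened
#' to its `I x J` columns first.
#'
#' @param x A [scattered_spectra] or [spectra_grid] object.
#' @param path Output CSV path.
#' @param sidecar_path Output sidecar path (JSON), defaulting to `path`
#'   with extension `.json`.
#' @return Invisibly, `path`.
#' @export
write_spectra_csv <- function(x, path,
                              sidecar_path = paste0(
                                tools::file_path_sans_ext(path), ".json")) {
  if (inherits(x, "spectra_grid")) x <- grid_to_scattered(x)
  if (!inherits(x, "scattered_spectra")) {
    stop_ternafac("x must be a scattered_spectra or spectra_grid")
  }
  if (ncol(x$absorbance) == 0L) stop_ternafac("empty set: nothing to write")
  lab <- x$concentrations$label
  if (anyDuplicated(lab)) {
    lab <- make.unique(lab, sep = "_")
  }
  tab <- data.frame(wavenumber = x$wavenumbers, check.names = FALSE)
  tab[lab] <- as.data.frame(x$absorbance)
  utils::write.csv(format(tab, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  meta <- stats::setNames(lapply(seq_along(lab), function(i) {
    list(c_nma = x$concentrations$c_nma[i],
         c_osm = x$concentrations$c_osm[i])
  }), lab)
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a single spectrum from a JCAMP-DX file
#'
#' Minimal reader for the `##XYDATA=(X++(Y..Y))` dialect: each data line
#' carries one abscissa value followed by ordinates at `DELTAX` spacing,
#' scaled by `XFACTOR`/`YFACTOR`. Intended for pure-water reference
#' spectra exported by spectrometer software.
#'
#' @param path JCAMP-DX file path.
#' @param c_nma,c_osm Composition to attach (defaults: pure water).
#' @return A [ftir_spectrum].
#' @export
read_jcampdx <- function(path, c_nma = 0, c_osm = 0) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(key, default = NA_real_) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(hit)) return(default)
    as.numeric(sub(paste0("^##", key, "="), "", hit[1]))
  }
  xfac <- get_field("XFACTOR", 1); yfac <- get_field("YFACTOR", 1)
  npts <- get_field("NPOINTS")
  start <- grep("^##XYDATA=\\(X\\+\\+\\(Y\\.\\.Y\\)\\)", lines)
  if (!length(start)) stop_ternafac("no ##XYDATA=(X++(Y..Y)) block in ", path)
  endmark <- grep("^##END", lines)
  endmark <- endmark[endmark > start[1]]
  body <- lines[(start[1] + 1):(if (length(endmark)) endmark[1] - 1
                                else length(lines))]
  body <- body[nzchar(trimws(body))]
  xs <- numeric(0); ys <- numeric(0)
  for (ln in body) {
    vals <- as.numeric(strsplit(trimws(ln), "[[:space:],]+")[[1]])
    if (anyNA(vals) || length(vals) < 2L) {
      stop_ternafac("unparseable JCAMP data line: ", ln)
    }
    xs <- c(xs, vals[1]); ys <- c(ys, list(vals[-1]))
  }
  ny <- lengths(ys)
  # reconstruct per-point abscissae from line starts and DELTAX
  deltax <- get_field("DELTAX")
  if (is.na(deltax)) {
    if (length(xs) < 2L) stop_ternafac("cannot infer DELTAX")
    deltax <- (xs[2] - xs[1]) / ny[1]
  }
  w <- unlist(lapply(seq_along(xs), function(i) {
    xs[i] + deltax * (seq_len(ny[i]) - 1)
  })) * xfac
  a <- unlist(ys) * yfac
  if (!is.na(npts) && length(w) != npts) {
    warning("JCAMP NPOINTS (", npts, ") != points read (", length(w), ")")
  }
  ftir_spectrum(w, a, c_nma = c_nma, c_osm = c_osm,
                label = basename(path))
}

#' Serialize a CP model to JSON
#'
#' Stores the wavenumber axis, per-factor loading arrays and fit
#' diagnostics; [read_cp_model()] restores an equivalent object.
#'
#' @param model A `cp_model` from [cp_als()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_cp_model <- function(model, path) {
  stopifnot(inherits(model, "cp_model"))
  out <- list(
    rank = model$rank,
    wavenumbers = model$wavenumbers,
    spectral_loadings = apply(model$A, 2, identity, simplify = FALSE),
    conc1_loadings = apply(model$B, 2, identity, simplify = FALSE),
    conc2_loadings = apply(model$C, 2, identity, simplify = FALSE),
    rel_error = model$rel_error,
    n_iterations = model$n_iterations,
    converged = model$converged,
    restart_congruence = model$restart_congruence)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a CP model back from JSON
#' @param path JSON path written by [write_cp_model()].
#' @return A `cp_model` object.
#' @export
read_cp_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  bindcols <- function(x) do.call(cbind, lapply(x, unlist))
  new_cp_model(rank = raw$rank,
               wavenumbers = unlist(raw$wavenumbers),
               A = bindcols(raw$spectral_loadings),
               B = bindcols(raw$conc1_loadings),
               C = bindcols(raw$conc2_loadings),
               rel_error = raw$rel_error,
               n_iterations = raw$n_iterations,
               converged = raw$converged,
               restart_congruence = raw$restart_congruence)
}
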