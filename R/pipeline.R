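# Config-driven orchestration: simulate/load -> regrid -> subtract ->
# derivative -> decompose -> classify, on both isolated series, with a
# machine-readable run report. Identical config + seed gives an
# identical report.

#' Pipeline run configuration
#'
#' Collects every tunable of the analysis chain in one validated
#' object, so a run report can record all of them and a run is fully
#' reproducible from config + seed. Input is either a built-in
#' synthetic scenario (`scenario`) or measured data (`set` +
#' `water_ref`, e.g. from [read_spectra_csv()] and [read_jcampdx()]).
#'
#' @param scenario `"stabilizer"`, `"denaturant"` or `"ideal"`, or
#'   `NULL` when supplying measured data.
#' @param set A [scattered_spectra] (ignored when `scenario` is set).
#' @param water_ref Pure-water reference [ftir_spectrum].
#' @param seed Integer master seed for simulation and decomposition.
#' @param noise_sd,jitter_sd Scenario noise/jitter (scenario input
#'   only); `NULL` keeps the scenario defaults.
#' @param window Optional `c(min, max)` wavenumber window (cm^-1) to
#'   truncate to before any analysis; `NULL` keeps the full axis.
#' @param water A [water_model]; for scenario input the scenario's own
#'   model is used so that generation and subtraction share one code
#'   path.
#' @param levels_per_axis,shrink_factor Target-grid parameters
#'   ([default_target_grid()]).
#' @param method,k_neighbors Interpolation parameters
#'   ([interpolate_grid()]).
#' @param r_min,r_max,redundancy_threshold,fit_gain_threshold
#'   Rank-scan parameters ([select_rank()]).
#' @param n_restarts,max_iter,tol CP-ALS parameters ([cp_als()]).
#' @param classify_threshold Congruence threshold of
#'   [classify_factors()].
#' @param out_dir Optional directory; when set, every stage artifact
#'   (grid, isolated series, components, derivatives, models, report)
#'   is written there as CSV/JSON.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = NULL, set = NULL,
                            water_ref = NULL, seed = 1L,
                            noise_sd = NULL, jitter_sd = NULL,
                            window = NULL,
                            water = water_model(),
                            levels_per_axis = 5, shrink_factor = 0.9,
                            method = "piecewise_linear",
                            k_neighbors = 6L,
                            r_min = 2L, r_max = 6L,
                            redundancy_threshold = 0.98,
                            fit_gain_threshold = 1e-3,
                            n_restarts = 10L, max_iter = 2000L,
                            tol = 1e-10,
                            classify_threshold = 0.95,
                            out_dir = NULL) {
  if (is.null(scenario) && (is.null(set) || is.null(water_ref))) {
    stop_ternafac("either a scenario name or set + water_ref required")
  }
  if (!is.null(scenario)) {
    scenario <- match.arg(scenario,
                          c("stabilizer", "denaturant", "ideal"))
  }
  if (!is.null(window) &&
      (length(window) != 2L || window[1] >= window[2])) {
    stop_ternafac("window must be c(min, max) with min < max")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML map onto [pipeline_config()] arguments;
#' `water` may be a map with `pure_water_molarity`, `vbar_nma`,
#' `vbar_osm`; measured input is given as `spectra_csv`, `sidecar` and
#' `water_ref_csv`/`water_ref_jcamp` paths.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  args$spectra_csv <- args$sidecar <- NULL
  args$water_ref_csv <- args$water_ref_jcamp <- NULL
  if (!is.null(y$water)) args$water <- do.call(water_model, y$water)
  if (!is.null(y$window)) args$window <- as.numeric(unlist(y$window))
  if (!is.null(y$spectra_csv)) {
    args$set <- if (!is.null(y$sidecar)) {
      read_spectra_csv(y$spectra_csv, y$sidecar)
    } else read_spectra_csv(y$spectra_csv)
    if (!is.null(y$water_ref_jcamp)) {
      args$water_ref <- read_jcampdx(y$water_ref_jcamp)
    } else if (!is.null(y$water_ref_csv)) {
      wr <- read_spectra_csv(y$water_ref_csv)
      args$water_ref <- get_spectrum(wr, 1L)
    } else stop_ternafac("a water reference file is required")
  }
  do.call(pipeline_config, args)
}

truncate_window <- function(x, window) {
  if (is.null(window)) return(x)
  keep <- x$wavenumbers >= window[1] & x$wavenumbers <= window[2]
  if (sum(keep) < 8L) stop_ternafac("window leaves fewer than 8 points")
  if (inherits(x, "scattered_spectra")) {
    return(scattered_spectra(x$wavenumbers[keep],
                             x$absorbance[keep, , drop = FALSE],
                             x$concentrations, x$design_note))
  }
  if (inherits(x, "ftir_spectrum")) {
    return(ftir_spectrum(x$wavenumbers[keep], x$absorbance[keep],
                         x$c_nma, x$c_osm, x$label))
  }
  stop_ternafac("cannot window object of class ", class(x)[1])
}

binary_edge <- function(set, solute) {
  conc <- set$concentrations
  keep <- if (solute == "nma") conc$c_osm == 0 else conc$c_nma == 0
  subset_spectra(set, keep)
}

analyse_isolated <- function(tensor_grid, cfg, seed_offset, pures,
                             derivs, own_mode) {
  scan <- select_rank(tensor_grid, r_min = cfg$r_min, r_max = cfg$r_max,
                      redundancy_threshold = cfg$redundancy_threshold,
                      fit_gain_threshold = cfg$fit_gain_threshold,
                      references = c(pures, derivs),
                      own_mode = own_mode,
                      seed = cfg$seed + seed_offset,
                      n_restarts = cfg$n_restarts,
                      max_iter = cfg$max_iter, tol = cfg$tol)
  model <- scan$models[[as.character(scan$chosen_rank)]]
  labels <- classify_factors(model, pures, derivs,
                             threshold = cfg$classify_threshold)
  list(scan = scan, model = model, labels = labels)
}

#' Run the full ternary-solution analysis chain
#'
#' Executes, in order: input acquisition (synthetic scenario or
#' supplied series), optional wavenumber windowing, interpolation onto
#' the evenly spaced concentration grid, water subtraction, per-molar
#' component estimation from the binary design edges, solute
#' subtraction into the two isolated series, derivative spectra of
#' both solutes, rank-scanned CP decomposition of each isolated
#' series, and factor classification against the pure and derivative
#' references of all components. Every stage failure aborts with the
#' stage name.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `run_report`: configuration echo, the
#'   target grid, component and derivative spectra, and per isolated
#'   series (`nma_isolated`, `osm_isolated`) the rank scan, chosen CP
#'   model and factor labels.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_ternafac("pipeline stage '", name, "' failed: ",
                    conditionMessage(e))
    })
  }

  truth <- NULL
  if (!is.null(cfg$scenario)) {
    sim <- stage("simulate", {
      fn <- switch(cfg$scenario, stabilizer = stabilizer_scenario,
                   denaturant = denaturant_scenario,
                   ideal = ideal_scenario)
      extra <- list(seed = cfg$seed)
      if (!is.null(cfg$noise_sd)) extra$noise_sd <- cfg$noise_sd
      if (!is.null(cfg$jitter_sd)) extra$jitter_sd <- cfg$jitter_sd
      do.call(fn, extra)
    })
    set <- sim$set; truth <- sim$truth
    water_ref <- truth$water_ref
    wmodel <- truth$water
  } else {
    set <- cfg$set; water_ref <- cfg$water_ref; wmodel <- cfg$water
  }

  set <- stage("window", truncate_window(set, cfg$window))
  water_ref <- stage("window", truncate_window(water_ref, cfg$window))
  stage("axis check", require_common_axis(set, water_ref,
                                          what = "series and water"))

  tgrid <- stage("target grid",
                 default_target_grid(set, cfg$levels_per_axis,
                                     cfg$shrink_factor))
  grid <- stage("regrid",
                interpolate_grid(set, tgrid, method = cfg$method,
                                 k_neighbors = cfg$k_neighbors))
  grid_w <- stage("water subtraction",
                  subtract_water(grid, water_ref, wmodel))

  edge_nma <- stage("binary edges", binary_edge(set, "nma"))
  edge_osm <- stage("binary edges", binary_edge(set, "osmolyte"))
  comp_nma <- stage("component estimation",
                    estimate_component_spectrum(edge_nma, water_ref,
                                                wmodel, "nma"))
  comp_osm <- stage("component estimation",
                    estimate_component_spectrum(edge_osm, water_ref,
                                                wmodel, "osmolyte"))

  nma_isolated <- stage("solute subtraction",
                        subtract_solute(grid_w, comp_osm, "osmolyte"))
  osm_isolated <- stage("solute subtraction",
                        subtract_solute(grid_w, comp_nma, "nma"))

  deriv_nma <- stage("derivative", suppressMessages(
    derivative_spectrum(subtract_water(edge_nma, water_ref, wmodel),
                        "nma")))
  deriv_osm <- stage("derivative", suppressMessages(
    derivative_spectrum(subtract_water(edge_osm, water_ref, wmodel),
                        "osmolyte")))

  pures <- list(comp_nma, comp_osm)
  derivs <- list(deriv_nma, deriv_osm)
  res_nma <- stage("decomposition (NMA-isolated)",
                   analyse_isolated(nma_isolated, cfg, 1000L, pures,
                                    derivs, own_mode = "B"))
  res_osm <- stage("decomposition (osmolyte-isolated)",
                   analyse_isolated(osm_isolated, cfg, 2000L, pures,
                                    derivs, own_mode = "C"))

  report <- structure(list(
    seed = cfg$seed,
    scenario = cfg$scenario,
    parameters = list(
      levels_per_axis = cfg$levels_per_axis,
      shrink_factor_requested = cfg$shrink_factor,
      shrink_factor_used = tgrid$shrink_factor,
      method = cfg$method, k_neighbors = cfg$k_neighbors,
      water = unclass(wmodel), window = cfg$window,
      r_min = cfg$r_min, r_max = cfg$r_max,
      redundancy_threshold = cfg$redundancy_threshold,
      fit_gain_threshold = cfg$fit_gain_threshold,
      n_restarts = cfg$n_restarts, max_iter = cfg$max_iter,
      tol = cfg$tol, classify_threshold = cfg$classify_threshold),
    n_input_spectra = n_spectra(set),
    target_grid = tgrid,
    components = list(nma = comp_nma, osmolyte = comp_osm),
    derivatives = list(nma = deriv_nma, osmolyte = deriv_osm),
    nma_isolated = res_nma,
    osm_isolated = res_osm,
    truth = truth), class = "run_report")

  if (!is.null(cfg$out_dir)) write_report_artifacts(report, grid,
                                                    nma_isolated,
                                                    osm_isolated,
                                                    cfg$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report",
      if (!is.null(x$scenario)) paste0(" (scenario: ", x$scenario, ")"),
      "\n", sep = "")
  cat(sprintf("  %d input spectra -> %dx%d grid\n", x$n_input_spectra,
              length(x$target_grid$c1_levels),
              length(x$target_grid$c2_levels)))
  for (nm in c("nma_isolated", "osm_isolated")) {
    r <- x[[nm]]
    cat(sprintf("  %s: rank %d (%s), labels: %s\n", nm,
                r$scan$chosen_rank, r$scan$stopping_reason,
                paste(r$labels$label, collapse = ", ")))
  }
  invisible(x)
}

write_report_artifacts <- function(report, grid, nma_isolated,
                                   osm_isolated, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_spectra_csv(grid, p("grid.csv"))
  write_spectra_csv(nma_isolated, p("nma_isolated.csv"))
  write_spectra_csv(osm_isolated, p("osm_isolated.csv"))
  w <- report$components$nma$wavenumbers
  utils::write.csv(data.frame(
    wavenumber = w,
    epsilon_nma = report$components$nma$epsilon,
    epsilon_osm = report$components$osmolyte$epsilon,
    deriv_nma = report$derivatives$nma$d_molar_absorbance,
    deriv_osm = report$derivatives$osmolyte$d_molar_absorbance),
    p("references.csv"), row.names = FALSE)
  for (nm in c("nma_isolated", "osm_isolated")) {
    res <- report[[nm]]
    write_cp_model(res$model, p(paste0(nm, "_model.json")))
    utils::write.csv(cbind(data.frame(wavenumber = w),
                           as.data.frame(res$model$A)),
                     p(paste0(nm, "_factors.csv")), row.names = FALSE)
    utils::write.csv(res$labels, p(paste0(nm, "_labels.csv")),
                     row.names = FALSE)
  }
  summary <- list(
    seed = report$seed, scenario = report$scenario,
    parameters = report$parameters,
    n_input_spectra = report$n_input_spectra,
    grid = list(c1_levels = report$target_grid$c1_levels,
                c2_levels = report$target_grid$c2_levels),
    results = lapply(report[c("nma_isolated", "osm_isolated")],
                     function(r) list(
                       chosen_rank = r$scan$chosen_rank,
                       stopping_reason = r$scan$stopping_reason,
                       rel_errors = as.list(r$scan$rel_errors),
                       labels = r$labels$label,
                       restart_congruence =
                         r$model$restart_congruence)),
    checksums = as.list(tools::md5sum(list.files(out_dir,
                                                 full.names = TRUE,
                                                 pattern = "\\.csv$"))))
  jsonlite::write_json(summary, p("run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Plot the factor spectra of a run report
#'
#' One panel per isolated series: fitted factor spectra overlaid with
#' the pure component and derivative reference spectra (all scaled to
#' comparable height). Files are named deterministically; plotting is
#' best-effort and never fails the run.
#'
#' @param report A `run_report`.
#' @param dir Output directory for PNG files.
#' @return Invisibly, the written file paths (possibly empty).
#' @export
plot_report <- function(report, dir = ".") {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in c("nma_isolated", "osm_isolated")) {
    f <- file.path(dir, paste0("factors_", nm, ".png"))
    ok <- tryCatch({
      res <- report[[nm]]
      w <- report$components$nma$wavenumbers
      A <- res$model$A
      grDevices::png(f, width = 900, height = 600)
      scl <- function(v) if (max(abs(v)) == 0) v else v / max(abs(v))
      graphics::matplot(w, apply(A, 2, scl), type = "l", lty = 1,
                        lwd = 2, xlab = "wavenumber / cm-1",
                        ylab = "scaled loading",
                        main = paste("CP factors:", nm))
      graphics::lines(w, scl(report$components$nma$epsilon),
                      col = "grey40", lty = 2)
      graphics::lines(w,
                      scl(report$derivatives$nma$d_molar_absorbance),
                      col = "grey40", lty = 3)
      graphics::legend("topleft", bty = "n", cex = 0.8,
                       legend = c(paste("factor", seq_len(ncol(A)),
                                        res$labels$label),
                                  "pure NMA (ref)", "d/dc NMA (ref)"),
                       lty = c(rep(1, ncol(A)), 2, 3),
                       col = c(seq_len(ncol(A)), "grey40", "grey40"))
      grDevices::dev.off()
      TRUE
    }, error = function(e) {
      if (grDevices::dev.cur() > 1) grDevices::dev.off()
      warning("plot for ", nm, " skipped: ", conditionMessage(e))
      FALSE
    })
    if (ok) files <- c(files, f)
  }
  invisible(files)
}
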