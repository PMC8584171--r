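# Synthetic ternary FTIR scenarios with closed-form ground truth.
#
# Absorbance model (Beer-Lambert mixing plus quadratic departures):
#   A(v; c1, c2) = c_w(c1,c2) * eps_w(v) + c1 * eps_1(v) + c2 * eps_2(v)
#                + k_self1 * c1^2 * s1(v) + k_self2 * c2^2 * s2(v)
#                + [bilinear scenarios] k_int * c1 * c2 * g(v)
#                + N(0, noise_sd)
# with c_w from the same volume-additivity model the isolation module
# uses, so ideal subtraction cancels the water term by construction.

#' Gaussian band specification
#'
#' @param center Band center, cm^-1.
#' @param width Gaussian sigma, cm^-1 (> 0).
#' @param height Peak height; AU per mol dm^-3 for component bands,
#'   dimensionless for the unit shapes scaled by a coupling constant.
#'   Negative heights are allowed (difference-band lobes).
#' @return A `band` object (named numeric vector).
#' @export
band <- function(center, width, height) {
  if (width <= 0) stop_ternafac("band width must be positive")
  structure(c(center = center, width = width, height = height),
            class = "band")
}

#' Evaluate a sum of Gaussian bands on a wavenumber axis
#'
#' @param wavenumbers Wavenumber axis, cm^-1.
#' @param bands A list of [band()] objects (possibly empty).
#' @return Numeric vector of the summed band profile.
#' @export
eval_bands <- function(wavenumbers, bands) {
  out <- numeric(length(wavenumbers))
  for (b in bands) {
    out <- out + b["height"] *
      exp(-(wavenumbers - b["center"])^2 / (2 * b["width"]^2))
  }
  unname(out)
}

#' Configuration of a synthetic ternary-solution scenario
#'
#' Defaults emulate the experimental design the package targets: a full
#' factorial 6 x 6 grid of NMA and osmolyte concentrations spanning
#' 0-2 mol dm^-3 (36 solutions including pure water), spectra on a
#' 1250-1800 cm^-1 window at 2 cm^-1 spacing, a broad water OH-bending
#' band near 1640 cm^-1, an NMA-like component with amide I/II and
#' C-N / C-H bands (1625, 1580, 1420, 1330 cm^-1) and a
#' stabilizer-like osmolyte without amide-region bands. Band heights
#' are fixture choices on the scale of real ATR absorbances
#' (0.1-1 AU at the grid maximum).
#'
#' Quadratic departures from Beer-Lambert mixing are available in two
#' forms: per-solute self-association (`k_self * c^2 * s(v)`, giving a
#' nonzero, closed-form derivative spectrum) and a bilinear
#' solute-solute interaction (`k_int * c1 * c2 * g(v)` with a wave-like
#' positive/negative difference band), switched by `interaction`.
#'
#' @param wavenumber_min,wavenumber_max,wavenumber_step Spectral window
#'   and spacing, cm^-1.
#' @param c1_levels,c2_levels Nominal design levels, mol dm^-3.
#' @param water_bands,nma_bands,osm_bands Lists of [band()]s defining
#'   per-molar component spectra (heights: AU per mol dm^-3).
#' @param nma_self_bands,osm_self_bands Unit shapes `s(v)` of the
#'   self-association difference bands.
#' @param k_self_nma,k_self_osm Self-association couplings,
#'   AU dm^6 mol^-2.
#' @param interaction `"none"` or `"bilinear"`.
#' @param interaction_bands Unit shape `g(v)` of the interaction band.
#' @param k_int Interaction coupling, AU dm^6 mol^-2.
#' @param jitter_sd Preparation error on nonzero nominal concentrations,
#'   mol dm^-3 (resampled until non-negative; nominal zeros stay exact:
#'   a solute that was never added carries no weighing error).
#' @param noise_sd Additive absorbance noise, AU.
#' @param water A [water_model]; the generator and the isolation stage
#'   share this code path.
#' @param seed Integer seed; fully determines the output.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(wavenumber_min = 1250, wavenumber_max = 1800,
                            wavenumber_step = 2,
                            c1_levels = seq(0, 2, length.out = 6),
                            c2_levels = seq(0, 2, length.out = 6),
                            water_bands = list(band(1640, 80, 1.0 / 55.345)),
                            nma_bands = list(band(1625, 12, 0.32),
                                             band(1580, 14, 0.18),
                                             band(1420, 10, 0.12),
                                             band(1330, 9, 0.07)),
                            osm_bands = list(band(1480, 10, 0.16),
                                             band(1395, 12, 0.10)),
                            nma_self_bands = list(band(1637, 10, 1),
                                                  band(1613, 10, -1)),
                            osm_self_bands = list(band(1488, 9, 1),
                                                  band(1470, 9, -1)),
                            k_self_nma = 0.02, k_self_osm = 0.015,
                            interaction = c("none", "bilinear"),
                            interaction_bands = list(band(1665, 8, 1),
                                                     band(1642, 8, -1)),
                            k_int = 0.05,
                            jitter_sd = 0.01, noise_sd = 2e-4,
                            water = water_model(vbar_nma = 0.077,
                                                vbar_osm = 0.072),
                            seed = 1L) {
  interaction <- match.arg(interaction)
  w <- seq(wavenumber_min, wavenumber_max, by = wavenumber_step)
  if (length(w) < 8L) {
    stop_ternafac("degenerate wavenumber window: fewer than 8 points")
  }
  for (b in c(water_bands, nma_bands, osm_bands)) {
    if (b["center"] < wavenumber_min || b["center"] > wavenumber_max) {
      stop_ternafac("band center ", b["center"],
                    " outside the wavenumber window")
    }
  }
  stopifnot(jitter_sd >= 0, noise_sd >= 0, k_int >= 0)
  structure(list(
    wavenumbers = w,
    c1_levels = sort(c1_levels), c2_levels = sort(c2_levels),
    water_bands = water_bands, nma_bands = nma_bands,
    osm_bands = osm_bands,
    nma_self_bands = nma_self_bands, osm_self_bands = osm_self_bands,
    k_self_nma = k_self_nma, k_self_osm = k_self_osm,
    interaction = interaction, interaction_bands = interaction_bands,
    k_int = k_int,
    jitter_sd = jitter_sd, noise_sd = noise_sd,
    water = water, seed = as.integer(seed)),
    class = "scenario_config")
}

# jitter one nonzero nominal concentration, resampling until >= 0
jitter_conc <- function(c_nominal, sd) {
  if (c_nominal == 0 || sd == 0) return(c_nominal)
  repeat {
    val <- c_nominal + stats::rnorm(1L, 0, sd)
    if (val >= 0) return(val)
  }
}

# closed-form noiseless absorbance matrix at given exact compositions
closed_form_absorbance <- function(config, c1, c2) {
  w <- config$wavenumbers
  eps_w <- eval_bands(w, config$water_bands)
  eps_1 <- eval_bands(w, config$nma_bands)
  eps_2 <- eval_bands(w, config$osm_bands)
  s1 <- eval_bands(w, config$nma_self_bands)
  s2 <- eval_bands(w, config$osm_self_bands)
  g <- eval_bands(w, config$interaction_bands)
  cw <- water_concentration(c1, c2, config$water)
  A <- outer(eps_w, cw) + outer(eps_1, c1) + outer(eps_2, c2) +
    config$k_self_nma * outer(s1, c1^2) +
    config$k_self_osm * outer(s2, c2^2)
  if (config$interaction == "bilinear") {
    A <- A + config$k_int * outer(g, c1 * c2)
  }
  A
}

#' Generate a synthetic ternary spectra series with ground truth
#'
#' Simulates the full-factorial concentration design of a ternary
#' (NMA-water-osmolyte) FTIR experiment: nominal compositions are
#' perturbed by preparation jitter, absorbances follow the closed-form
#' mixing model described in [scenario_config()], and additive detector
#' noise is applied last. The returned ground truth is sufficient to
#' compute every intermediate of the analysis pipeline in closed form,
#' which makes it the oracle for all downstream tests.
#'
#' @param config A [scenario_config()].
#' @return A list with elements `set` (a [scattered_spectra]) and
#'   `truth` (exact compositions, per-molar [component_spectrum]s, the
#'   pure-water reference spectrum, planted self-association and
#'   interaction shapes with their couplings, and the [water_model]).
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)
  w <- config$wavenumbers
  design <- expand.grid(c_nma = config$c1_levels,
                        c_osm = config$c2_levels,
                        KEEP.OUT.ATTRS = FALSE)
  c1 <- vapply(design$c_nma, jitter_conc, 0, sd = config$jitter_sd)
  c2 <- vapply(design$c_osm, jitter_conc, 0, sd = config$jitter_sd)
  A <- closed_form_absorbance(config, c1, c2)
  if (config$noise_sd > 0) {
    A <- A + matrix(stats::rnorm(length(A), 0, config$noise_sd),
                    nrow = nrow(A))
  }
  conc <- data.frame(c_nma = c1, c_osm = c2,
                     label = sprintf("n%g_o%g", design$c_nma, design$c_osm))
  set <- scattered_spectra(w, A, conc,
                           design_note = sprintf(
                             "synthetic %s scenario, seed %d",
                             config$interaction, config$seed))
  cw_pure <- config$water$pure_water_molarity
  eps_w <- eval_bands(w, config$water_bands)
  truth <- list(
    config = config,
    nominal = design, c_nma = c1, c_osm = c2,
    c_water = water_concentration(c1, c2, config$water),
    components = list(
      water = component_spectrum(w, eps_w, "water",
                                 reference_concentration = cw_pure),
      nma = component_spectrum(w, eval_bands(w, config$nma_bands), "nma"),
      osmolyte = component_spectrum(w, eval_bands(w, config$osm_bands),
                                    "osmolyte")),
    water_ref = ftir_spectrum(w, cw_pure * eps_w, 0, 0, "pure water"),
    self_shape_nma = eval_bands(w, config$nma_self_bands),
    self_shape_osm = eval_bands(w, config$osm_self_bands),
    k_self_nma = config$k_self_nma, k_self_osm = config$k_self_osm,
    interaction_shape = eval_bands(w, config$interaction_bands),
    k_int = if (config$interaction == "bilinear") config$k_int else 0,
    water = config$water)
  list(set = set, truth = truth)
}

#' Canonical test scenarios: ideal, stabilizer, denaturant
#'
#' Three ready-made study conditions used throughout the test-suite and
#' the acceptance pipeline:
#'
#' * `ideal_scenario()`: pure Beer-Lambert mixing (no self-association,
#'   no interaction). Every spectrum is an affine function of the two
#'   concentrations, so interpolation and the two-stage subtraction are
#'   exact and the complete residual is zero.
#' * `stabilizer_scenario()`: the solutes avoid each other -- no
#'   bilinear interaction term. NMA carries a self-association
#'   difference band, the osmolyte mixes ideally, so each isolated
#'   series is exactly trilinear of rank 2 (pure component +
#'   concentration-change factor) in the noise-free limit.
#' * `denaturant_scenario()`: adds a bilinear NMA-osmolyte interaction
#'   with a wave-like difference band, making each isolated series
#'   exactly rank 3, the extra factor being the interaction factor.
#'
#' @param seed Integer seed.
#' @param noise_sd,jitter_sd Noise and preparation-jitter levels,
#'   passed to [scenario_config()].
#' @param ... Further overrides for [scenario_config()].
#' @return A `list(set, truth)` as from [generate_scenario()].
#' @export
stabilizer_scenario <- function(seed = 1L, noise_sd = 2e-4,
                                jitter_sd = 0.01, ...) {
  generate_scenario(scenario_config(
    interaction = "none", k_self_osm = 0,
    noise_sd = noise_sd, jitter_sd = jitter_sd, seed = seed, ...))
}

#' @rdname stabilizer_scenario
#' @export
denaturant_scenario <- function(seed = 1L, noise_sd = 2e-4,
                                jitter_sd = 0.01, ...) {
  generate_scenario(scenario_config(
    interaction = "bilinear", k_self_osm = 0,
    noise_sd = noise_sd, jitter_sd = jitter_sd, seed = seed, ...))
}

#' @rdname stabilizer_scenario
#' @export
ideal_scenario <- function(seed = 1L, noise_sd = 0, jitter_sd = 0.01,
                           ...) {
  generate_scenario(scenario_config(
    interaction = "none", k_self_nma = 0, k_self_osm = 0,
    noise_sd = noise_sd, jitter_sd = jitter_sd, seed = seed, ...))
}
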