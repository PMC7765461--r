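#' Configuration for the synthetic grass-canopy generator
#'
#' The generator emulates top-of-canopy perennial-ryegrass reflectance in
#' 550--790 nm as a function of a latent biomass variable: a gently
#' declining visible segment (chlorophyll absorption deepens with
#' biomass), a sigmoidal red-edge rise, and a NIR plateau whose level
#' saturates with biomass (the leaf-area-index effect). Each sample is an
#' exact piecewise linear+logistic curve plus optional narrowband
#' perturbations that the piecewise model cannot represent, plus noise.
#'
#' Biomass-to-parameter maps (kg DM/ha in, reflectance fractions out):
#' * NIR plateau `K(b) = k0 + k1 * (1 - exp(-b / b_sat))` — saturating,
#'   with `b_sat = 1500` mirroring the observed loss of index sensitivity
#'   above ~1500 kg DM/ha.
#' * red level `r680(b) = red_base + red_amp * exp(-b / red_scale)` —
#'   decreasing in biomass (chlorophyll absorption).
#' * green level `r550(b) = green_base + green_amp * exp(-b / green_scale)`;
#'   the visible slope is `(r680 - r550) / 110` so the linear segment
#'   passes through both levels.
#' * red-edge growth rate `C(b) = c_base + c_amp * (1 - exp(-b / b_sat))`.
#'
#' @param n Sample count.
#' @param biomass_range Uniform biomass range, kg DM/ha.
#' @param locations `NULL` (single site), a character vector of labels, or
#'   a data frame with columns `label` and optionally `biomass_shift`
#'   (kg DM/ha added to that location's draws) and `spectral_offset`
#'   (constant reflectance offset, emulating site-specific calibration /
#'   background differences).
#' @param noise_sd Additive Gaussian noise sd (reflectance fraction).
#' @param heteroscedastic If `TRUE`, noise sd scales with reflectance
#'   (`noise_sd * R / 0.2`) instead of being constant.
#' @param narrowband Toggle narrowband perturbations: a fluorescence-like
#'   Gaussian bump near 760 nm (amplitude 0.01, FWHM 5 nm) and a random
#'   red-edge inflection wiggle near 720 nm, both deliberately outside the
#'   piecewise model family.
#' @param seed Integer seed; identical configs generate identical
#'   libraries.
#' @param k0,k1,b_sat,red_base,red_amp,red_scale,green_base,green_amp,green_scale,c_base,c_amp
#'   Biomass-to-parameter map constants (see above).
#' @param bump_center,bump_fwhm,bump_amp Fluorescence-like bump, nm / nm /
#'   reflectance.
#' @param inflect_center,inflect_fwhm,inflect_sd Red-edge inflection
#'   wiggle: Gaussian bump at `inflect_center` with per-sample amplitude
#'   drawn from `N(0, inflect_sd)`.
#' @param param_jitter Relative sd of per-sample lognormal-style scatter
#'   applied to each generating parameter around its biomass trend
#'   (`K`, `r550`, `r680`, `C` each multiplied by `1 + N(0, jitter)`).
#'   This models canopy-structure variability not explained by biomass
#'   (chlorophyll and leaf area are correlated with, not determined by,
#'   standing biomass); unlike measurement noise it stays inside the
#'   piecewise model family, so a correct retrieval can recover it.
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(n = 500L, biomass_range = c(100, 4000),
                             locations = NULL, noise_sd = 0.005,
                             heteroscedastic = FALSE, narrowband = FALSE,
                             seed = 1L,
                             k0 = 0.15, k1 = 0.45, b_sat = 1500,
                             red_base = 0.035, red_amp = 0.10,
                             red_scale = 1200,
                             green_base = 0.05, green_amp = 0.12,
                             green_scale = 1800,
                             c_base = 0.042, c_amp = 0.010,
                             bump_center = 760, bump_fwhm = 5,
                             bump_amp = 0.01,
                             inflect_center = 720, inflect_fwhm = 20,
                             inflect_sd = 0.004, param_jitter = 0.12) {
  if (length(biomass_range) != 2L || any(!is.finite(biomass_range)) ||
      biomass_range[1L] < 0 || diff(biomass_range) <= 0) {
    abort_ps("biomass_range must be a nonnegative increasing pair",
             "pasturespec_config_error")
  }
  if (!is.finite(seed)) {
    abort_ps("seed must be a finite integer", "pasturespec_config_error")
  }
  if (n < 1L) abort_ps("n must be >= 1", "pasturespec_config_error")
  if (noise_sd < 0) abort_ps("noise_sd must be >= 0",
                             "pasturespec_config_error")
  locations <- normalize_locations(locations)
  structure(list(
    n = as.integer(n), biomass_range = as.numeric(biomass_range),
    locations = locations, noise_sd = noise_sd,
    heteroscedastic = isTRUE(heteroscedastic),
    narrowband = isTRUE(narrowband), seed = as.integer(seed),
    k0 = k0, k1 = k1, b_sat = b_sat,
    red_base = red_base, red_amp = red_amp, red_scale = red_scale,
    green_base = green_base, green_amp = green_amp,
    green_scale = green_scale, c_base = c_base, c_amp = c_amp,
    bump_center = bump_center, bump_fwhm = bump_fwhm, bump_amp = bump_amp,
    inflect_center = inflect_center, inflect_fwhm = inflect_fwhm,
    inflect_sd = inflect_sd, param_jitter = param_jitter),
    class = "generator_config")
}

normalize_locations <- function(locations) {
  if (is.null(locations)) locations <- "siteA"
  if (is.character(locations)) {
    locations <- data.frame(label = locations, stringsAsFactors = FALSE)
  }
  locations <- as.data.frame(locations, stringsAsFactors = FALSE)
  if (is.null(locations$label)) {
    abort_ps("locations need a 'label' column", "pasturespec_config_error")
  }
  if (is.null(locations$biomass_shift)) locations$biomass_shift <- 0
  if (is.null(locations$spectral_offset)) locations$spectral_offset <- 0
  locations
}

# Biomass -> generating parameters (trend plus per-sample scatter).
generator_params <- function(cfg, b) {
  n <- length(b)
  jit <- function() {
    if (cfg$param_jitter > 0) {
      pmax(1 + stats::rnorm(n, 0, cfg$param_jitter), 0.5)
    } else rep(1, n)
  }
  list(
    K = (cfg$k0 + cfg$k1 * (1 - exp(-b / cfg$b_sat))) * jit(),
    r680 = (cfg$red_base + cfg$red_amp * exp(-b / cfg$red_scale)) * jit(),
    r550 = (cfg$green_base + cfg$green_amp * exp(-b / cfg$green_scale)) *
      jit(),
    C = (cfg$c_base + cfg$c_amp * (1 - exp(-b / cfg$b_sat))) * jit())
}

#' Generate a synthetic hyperspectral grass-canopy library
#'
#' Draws biomass uniformly in the configured range (plus any per-location
#' shift), maps it to piecewise-model parameters, emits the exact
#' piecewise spectrum on the grid, then adds the optional narrowband
#' perturbations, Gaussian noise and per-location spectral offsets, and
#' clips to `[0.001, 1]`. With `noise_sd = 0` and `narrowband = FALSE`
#' every emitted curve lies in the piecewise model family (its linear
#' segment passes through `r680` at 660 nm and its logistic segment has
#' asymptote `K`).
#'
#' @param cfg A [generator_config()].
#' @param grid Wavelength grid, default [wavelength_grid()].
#' @return A [spectral_library()] with `location` and `biomass` metadata;
#'   the generating ground truth (biomass, location, `K`, `r680`, `r550`,
#'   `C`, `beta`) is attached as attribute `"truth"`.
#' @export
generate_library <- function(cfg, grid = wavelength_grid()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n <- cfg$n
  loc_i <- sample.int(nrow(cfg$locations), n, replace = TRUE)
  b <- stats::runif(n, cfg$biomass_range[1L], cfg$biomass_range[2L]) +
    cfg$locations$biomass_shift[loc_i]
  b <- pmax(b, 1)
  pars <- generator_params(cfg, b)
  # any vegetated canopy keeps its NIR plateau above the red-absorption
  # level; guard the jittered draws so every curve has a rising red edge
  pars$K <- pmax(pars$K, pars$r680 * 1.2)
  beta <- (pars$r680 - pars$r550) / 110
  vals <- matrix(NA_real_, nrow = n, ncol = length(grid))
  for (i in seq_len(n)) {
    vals[i, ] <- piecewise_values(grid, pars$r550[i], beta[i],
                                  pars$r680[i], pars$K[i], pars$C[i])
  }
  if (cfg$narrowband) {
    bump_sd <- cfg$bump_fwhm / (2 * sqrt(2 * log(2)))
    bump <- cfg$bump_amp * exp(-0.5 * ((grid - cfg$bump_center) / bump_sd)^2)
    vals <- sweep(vals, 2L, bump, `+`)
    infl_sd <- cfg$inflect_fwhm / (2 * sqrt(2 * log(2)))
    infl_shape <- exp(-0.5 * ((grid - cfg$inflect_center) / infl_sd)^2)
    amp <- stats::rnorm(n, 0, cfg$inflect_sd)
    vals <- vals + outer(amp, infl_shape)
  }
  if (cfg$noise_sd > 0) {
    sd_mat <- if (cfg$heteroscedastic) cfg$noise_sd * pmax(vals, 0) / 0.2
              else cfg$noise_sd
    vals <- vals + stats::rnorm(length(vals)) * sd_mat
  }
  vals <- vals + cfg$locations$spectral_offset[loc_i]
  vals <- pmin(pmax(vals, 0.001), 1)
  ids <- sprintf("s%04d", seq_len(n))
  rownames(vals) <- ids
  meta <- data.frame(id = ids, location = cfg$locations$label[loc_i],
                     biomass = b, stringsAsFactors = FALSE)
  lib <- new_spectral_library(grid, vals, meta)
  attr(lib, "truth") <- data.frame(
    id = ids, location = meta$location, biomass = b,
    K = pars$K, r680 = pars$r680, r550 = pars$r550, C = pars$C,
    beta = beta, stringsAsFactors = FALSE)
  lib
}

#' Generate a synthetic band table in one call
#'
#' [generate_library()] followed by [band_table()]: the multispectral
#' observations a four-band camera would record over the synthetic
#' canopies, with biomass and location metadata attached.
#'
#' @param cfg A [generator_config()].
#' @param model A [sensor_model()].
#' @param grid Wavelength grid for the underlying spectra.
#' @return Data frame of band values plus metadata; the generating truth
#'   table is attached as attribute `"truth"`.
#' @export
generate_band_table <- function(cfg, model = sensor_model(),
                                grid = wavelength_grid()) {
  lib <- generate_library(cfg, grid)
  out <- band_table(lib, model)
  attr(out, "truth") <- attr(lib, "truth")
  out
}
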