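# YAML configuration readers for the command-line workflow.

#' Read a sensor definition from YAML
#'
#' Expected structure: a top-level `bands` list, each entry with `name`,
#' `center_nm`, `width_nm` and optional `shape`.
#'
#' @param path YAML file path.
#' @return A [sensor_model()].
#' @export
read_sensor_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$bands)) {
    abort_ps("sensor config needs a 'bands' list", "pasturespec_config_error")
  }
  bands <- lapply(cfg$bands, function(b) {
    sensor_band(b$name, b$center_nm, b$width_nm,
                shape = if (is.null(b$shape)) "boxcar" else b$shape)
  })
  sensor_model(bands)
}

#' Read a generator configuration from YAML
#'
#' Scalar fields map one-to-one onto [generator_config()] arguments, with
#' the sample count spelled `n_samples` (a bare `n` is a boolean in YAML
#' 1.1; it is tolerated but not recommended); `locations` may be a list
#' of `{label, biomass_shift, spectral_offset}` entries.
#'
#' @param path YAML file path.
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  nm <- names(cfg)
  nm[nm == "n_samples"] <- "n"
  nm[nm == "FALSE"] <- "n"  # unquoted 'n' key parsed as YAML boolean
  names(cfg) <- nm
  if (!is.null(cfg$locations)) {
    cfg$locations <- do.call(rbind, lapply(cfg$locations, function(l) {
      data.frame(label = l$label,
                 biomass_shift = l$biomass_shift %||% 0,
                 spectral_offset = l$spectral_offset %||% 0,
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(cfg$biomass_range)) {
    cfg$biomass_range <- as.numeric(unlist(cfg$biomass_range))
  }
  known <- names(formals(generator_config))
  do.call(generator_config, cfg[intersect(names(cfg), known)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
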