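# Broadband vegetation-index registry: the "current method" predictors,
# computed directly from the four camera bands (never from reconstructed
# spectra, keeping the current/proposed contrast clean). Since the sensor
# has no blue band, SIPI2 substitutes green for blue.
vi_registry <- list(
  ndvi  = function(b) (b$nir - b$red) / (b$nir + b$red),
  gndvi = function(b) (b$nir - b$green) / (b$nir + b$green),
  ndre  = function(b) (b$nir - b$red_edge) / (b$nir + b$red_edge),
  ngrdi = function(b) (b$green - b$red) / (b$green + b$red),
  lci   = function(b) (b$nir - b$red_edge) / (b$nir + b$red),
  sipi2 = function(b) (b$nir - b$green) / (b$nir - b$red)
)

#' Compute one broadband vegetation index
#'
#' Registry of the six indices of the current-method predictor set:
#' `ndvi`, `gndvi`, `ndre`, `ngrdi`, `lci`, `sipi2`. Formulas operate on
#' the four band reflectances; zero denominators yield `NA` with a
#' warning (the row is retained, not dropped).
#'
#' @param bands Named list / one-row data frame / `"band_values"` with
#'   `green`, `red`, `red_edge`, `nir`, or a multi-row band table (then a
#'   vector is returned).
#' @param name Index name.
#' @return Unitless index value(s).
#' @export
compute_vi <- function(bands, name) {
  name <- match.arg(tolower(name), names(vi_registry))
  b <- as.list(bands)
  vals <- vi_registry[[name]](b)
  bad <- !is.finite(vals)
  if (any(bad)) {
    warning(sprintf("%s undefined (zero denominator) for %d row(s)",
                    name, sum(bad)))
    vals[bad] <- NA_real_
  }
  vals
}

#' Current-method feature rows: six VIs plus the raw bands
#'
#' @param bands Band table (data frame from [band_table()]) or a single
#'   `"band_values"` object.
#' @return Data frame with `id`, the six vegetation indices, the four raw
#'   band values (`b_green`, `b_red`, `b_red_edge`, `b_nir`), and
#'   `location`/`biomass` carried through when present.
#' @export
current_features <- function(bands) {
  b <- if (inherits(bands, "band_values")) {
    as.data.frame(unclass(bands), stringsAsFactors = FALSE)
  } else {
    as.data.frame(bands, stringsAsFactors = FALSE)
  }
  out <- data.frame(id = if (is.null(b$id))
    sprintf("s%04d", seq_len(nrow(b))) else as.character(b$id),
    stringsAsFactors = FALSE)
  for (nm in names(vi_registry)) out[[nm]] <- compute_vi(b, nm)
  out$b_green <- b$green
  out$b_red <- b$red
  out$b_red_edge <- b$red_edge
  out$b_nir <- b$nir
  if (!is.null(b$location)) out$location <- b$location
  if (!is.null(b$biomass)) out$biomass <- b$biomass
  out
}
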