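#' Define a multispectral sensor band
#'
#' A band is described by its center, full bandwidth and response-function
#' shape. The "center/width" notation follows the datasheet convention of
#' small UAV multispectral cameras: a 550/40 band has support
#' `[530, 570]` nm. The discrete response function is renormalized on the
#' spectrum grid at convolution time so that a flat spectrum maps to its
#' own level.
#'
#' @param name Band name; the default sensor uses `green`, `red`,
#'   `red_edge`, `nir`.
#' @param center Band center, nm.
#' @param width Full bandwidth, nm (boxcar support width; Gaussian FWHM).
#' @param shape `"boxcar"` (default), `"gaussian"`, or `"delta"` (point
#'   sample at the grid point nearest the center, used for idealized
#'   sampling in validation work).
#' @return An object of class `"sensor_band"`.
#' @export
sensor_band <- function(name, center, width,
                        shape = c("boxcar", "gaussian", "delta")) {
  shape <- match.arg(shape)
  if (!is.finite(center) || !is.finite(width) || width < 0) {
    abort_ps("invalid band definition", "pasturespec_format_error")
  }
  structure(list(name = as.character(name), center = center, width = width,
                 shape = shape),
            class = "sensor_band")
}

#' A multispectral sensor as an ordered set of bands
#'
#' The default model mimics a common commercial four-band UAV camera:
#' green 550/40, red 660/40, red edge 735/10, NIR 790/40, all boxcar.
#'
#' @param bands List of [sensor_band()] objects with unique names. `NULL`
#'   gives the default four-band model.
#' @param shape Response shape applied to the default bands when `bands`
#'   is `NULL`.
#' @return An object of class `"sensor_model"`.
#' @export
sensor_model <- function(bands = NULL, shape = "boxcar") {
  if (is.null(bands)) {
    bands <- list(
      sensor_band("green", 550, 40, shape),
      sensor_band("red", 660, 40, shape),
      sensor_band("red_edge", 735, 10, shape),
      sensor_band("nir", 790, 40, shape))
  }
  nm <- vapply(bands, function(b) b$name, character(1L))
  if (anyDuplicated(nm)) {
    abort_ps("band names must be unique", "pasturespec_format_error")
  }
  names(bands) <- nm
  structure(list(bands = bands), class = "sensor_model")
}

#' @export
print.sensor_model <- function(x, ...) {
  cat("<sensor_model>\n")
  for (b in x$bands) {
    cat(sprintf("  %-9s %g/%g nm (%s)\n", b$name, b$center, b$width, b$shape))
  }
  invisible(x)
}

# Discrete, normalized SRF-times-quadrature weights for one band on a
# grid. Support falling partly outside the grid (the default green band's
# nominal [530, 570] on a 550 nm grid start, and likewise NIR at the 790 nm
# grid end) is clipped and the weights renormalized.
band_weights <- function(band, wavelengths) {
  n <- length(wavelengths)
  if (band$center < wavelengths[1L] || band$center > wavelengths[n]) {
    abort_ps(sprintf(
      "spectrum grid [%g, %g] nm does not cover band '%s' (center %g nm)",
      wavelengths[1L], wavelengths[n], band$name, band$center),
      "pasturespec_range_error")
  }
  if (band$shape == "delta") {
    w <- numeric(n)
    w[nearest_index(wavelengths, band$center)] <- 1
    return(w)
  }
  srf <- switch(band$shape,
    boxcar = as.numeric(wavelengths >= band$center - band$width / 2 &
                        wavelengths <= band$center + band$width / 2),
    gaussian = {
      sd <- band$width / (2 * sqrt(2 * log(2)))
      exp(-0.5 * ((wavelengths - band$center) / sd)^2)
    })
  w <- srf * trapezoid_weights(wavelengths)
  total <- sum(w)
  if (total <= 0) {
    abort_ps(sprintf("band '%s' has no support on the spectrum grid",
                     band$name), "pasturespec_range_error")
  }
  w / total
}

#' Convolve a spectrum to multispectral band values
#'
#' Each band value is the trapezoid-quadrature integral of reflectance
#' times the band's response function, renormalized on the discrete grid
#' (so a flat spectrum maps to its own level and convolution is linear in
#' the spectrum).
#'
#' @param s A [spectrum()].
#' @param model A [sensor_model()].
#' @return An object of class `"band_values"`: a list with `id` and one
#'   reflectance fraction per band.
#' @export
convolve_spectrum <- function(s, model = sensor_model()) {
  out <- lapply(model$bands, function(b) {
    sum(band_weights(b, s$wavelengths) * s$reflectance)
  })
  structure(c(list(id = s$id), out), class = "band_values")
}

#' Convolve every spectrum of a library
#'
#' @param lib A [spectral_library()].
#' @param model A [sensor_model()].
#' @return A data frame with one row per spectrum: `id`, one column per
#'   band, and the library's `location`/`biomass` metadata carried through.
#' @export
band_table <- function(lib, model = sensor_model()) {
  band_names <- names(model$bands)
  n <- nrow(lib$values)
  if (n == 0L) {
    out <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(band_names)), band_names))
    return(cbind(data.frame(id = character(0)), out))
  }
  W <- vapply(model$bands, band_weights, numeric(length(lib$wavelengths)),
              wavelengths = lib$wavelengths)
  vals <- lib$values %*% W
  out <- data.frame(id = rownames(lib$values), vals,
                    stringsAsFactors = FALSE, row.names = NULL)
  meta <- lib$metadata
  if (any(!is.na(meta$location))) out$location <- meta$location
  if (any(!is.na(meta$biomass))) out$biomass <- meta$biomass
  out
}
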