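#' Continuum removal by upper convex hull
#'
#' Normalizes a spectrum by the upper convex hull of its points so that
#' absorption features become comparable band depths on a 0--1 scale. The
#' hull is the concave majorant of `(lambda, R)` over the requested range,
#' computed with a monotone-chain sweep and interpolated linearly between
#' hull vertices; continuum-removed reflectance is `R / hull` (exactly 1
#' at the range endpoints) and band depth is `1 - R / hull`.
#'
#' @param s A [spectrum()].
#' @param range Two wavelengths (nm) bounding the feature; defaults to the
#'   full spectrum span. At least 3 grid points must fall inside.
#' @return An object of class `"continuum_result"`: `wavelengths`,
#'   `reflectance`, `hull`, `cr` (continuum-removed reflectance),
#'   `band_depth`, `Dc` (maximum band depth), `max_depth_position` (nm;
#'   ties broken toward the shortest wavelength) and `band_area`
#'   (trapezoid integral of band depth over the range, nm).
#' @export
continuum_remove <- function(s, range = NULL) {
  if (is.null(range)) range <- range(s$wavelengths)
  idx <- which(s$wavelengths >= min(range) & s$wavelengths <= max(range))
  if (length(idx) < 3L) {
    abort_ps("continuum removal needs at least 3 points in range",
             "pasturespec_range_error")
  }
  x <- s$wavelengths[idx]
  y <- s$reflectance[idx]
  if (max(y) <= 0) {
    abort_ps("all-zero reflectance in range: continuum undefined",
             "pasturespec_format_error")
  }
  h <- upper_hull_indices(x, y)
  hull <- stats::approx(x[h], y[h], xout = x, method = "linear",
                        ties = "ordered")$y
  hull <- pmax(hull, y)  # guard against interpolation round-off
  cr <- ifelse(hull > 0, pmin(y / hull, 1), 1)
  bd <- 1 - cr
  imax <- which.max(bd)  # first maximum = shortest wavelength on ties
  structure(list(
    wavelengths = x, reflectance = y, hull = hull, cr = cr,
    band_depth = bd, Dc = bd[imax], max_depth_position = x[imax],
    band_area = trapz(x, bd), range = c(min(range), max(range))),
    class = "continuum_result")
}

# Monotone-chain upper hull over points already sorted by x.
# Returns indices of the hull vertices, left to right.
upper_hull_indices <- function(x, y) {
  n <- length(x)
  h <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    while (k >= 2L) {
      o <- h[k - 1L]; a <- h[k]
      cross <- (x[a] - x[o]) * (y[i] - y[o]) - (y[a] - y[o]) * (x[i] - x[o])
      if (cross >= 0) k <- k - 1L else break  # pop non-right turns
    }
    k <- k + 1L
    h[k] <- i
  }
  h[seq_len(k)]
}

#' @export
print.continuum_result <- function(x, ...) {
  cat(sprintf(
    "<continuum_result> %g-%g nm, Dc=%.4g at %g nm, band_area=%.4g\n",
    x$range[1L], x$range[2L], x$Dc, x$max_depth_position, x$band_area))
  invisible(x)
}

#' Normalized band-depth index
#'
#' `NBDI(lambda) = (BD(lambda) - Dc) / (BD(lambda) + Dc)`: the band depth
#' at a chosen wavelength contrasted against the feature's maximum depth.
#' Lies in `[-1, 0]` whenever `Dc > 0`, reaching 0 exactly at the
#' maximum-depth position. For a flat spectrum (`BD + Dc = 0`) the index
#' is defined as 0, with a warning.
#'
#' @param cr_result A [continuum_remove()] result.
#' @param lambda Wavelength, nm; the nearest grid point is used.
#' @return Unitless index value.
#' @export
nbdi <- function(cr_result, lambda) {
  if (lambda < cr_result$range[1L] || lambda > cr_result$range[2L]) {
    abort_ps("NBDI wavelength outside continuum range",
             "pasturespec_range_error")
  }
  bd <- cr_result$band_depth[nearest_index(cr_result$wavelengths, lambda)]
  denom <- bd + cr_result$Dc
  if (denom == 0) {
    warning("flat spectrum: NBDI undefined, returning 0")
    return(0)
  }
  (bd - cr_result$Dc) / denom
}

#' Normalized ratio index of two narrowband reflectances
#'
#' `(R(lambda1) - R(lambda2)) / (R(lambda1) + R(lambda2))`; the default
#' 745/755 nm pair is the pasture-biomass-optimized ratio used in the
#' proposed feature set.
#'
#' @param s A [spectrum()].
#' @param lambda1,lambda2 Wavelengths, nm (nearest grid points used;
#'   exact on the canonical 1 nm grid).
#' @return Unitless index in `[-1, 1]`; `NA` with a warning when the
#'   denominator is zero.
#' @export
normalized_ratio_index <- function(s, lambda1 = 745, lambda2 = 755) {
  r1 <- s$reflectance[nearest_index(s$wavelengths, lambda1)]
  r2 <- s$reflectance[nearest_index(s$wavelengths, lambda2)]
  if (r1 + r2 == 0) {
    warning("zero denominator in normalized ratio index")
    return(NA_real_)
  }
  (r1 - r2) / (r1 + r2)
}

#' Proposed-method feature row for one reconstructed spectrum
#'
#' The continuum-removal feature set of the proposed workflow: band area
#' and its cube (cubic transforms damp the saturation of area-type
#' features at high biomass), the cubed wavelength position of maximum
#' band depth, normalized band-depth indices at 556 and 744 nm, the
#' optimized 745/755 normalized ratio index, and the two piecewise-fit
#' coefficients C and beta. The continuum spans the full 550--790 nm
#' reconstruction range so one hull supports both NBDI anchors.
#'
#' @param s A [spectrum()] on the reconstruction grid.
#' @param fit The matching `"piecewise_fit"` (or a list/one-row data frame
#'   providing `C` and `beta`).
#' @param range Continuum range, nm.
#' @return One-row data frame: `id`, `band_area`, `band_area_cubed`,
#'   `max_depth_position_cubed`, `nbdi_556`, `nbdi_744`, `optimized_nri`,
#'   `C`, `beta`.
#' @export
proposed_features <- function(s, fit, range = c(550, 790)) {
  cres <- continuum_remove(s, range = range)
  data.frame(
    id = s$id,
    band_area = cres$band_area,
    band_area_cubed = cres$band_area^3,
    max_depth_position_cubed = cres$max_depth_position^3,
    nbdi_556 = nbdi(cres, 556),
    nbdi_744 = nbdi(cres, 744),
    optimized_nri = normalized_ratio_index(s, 745, 755),
    C = as.numeric(fit$C),
    beta = as.numeric(fit$beta),
    stringsAsFactors = FALSE)
}

#' Proposed-method feature table for a reconstructed library
#'
#' @param lib A [spectral_library()] of reconstructed spectra.
#' @param fits Fit report from [reconstruct_library()] (matched by `id`).
#' @param range Continuum range, nm.
#' @return Data frame with one feature row per spectrum, plus `location`
#'   and `biomass` metadata when present.
#' @export
proposed_feature_table <- function(lib, fits, range = c(550, 790)) {
  rows <- lapply(seq_len(nrow(lib$values)), function(i) {
    s <- get_spectrum(lib, i)
    f <- fits[match(s$id, fits$id), , drop = FALSE]
    if (nrow(f) != 1L) {
      abort_ps(sprintf("no fit record for spectrum '%s'", s$id),
               "pasturespec_format_error")
    }
    proposed_features(s, f, range = range)
  })
  out <- do.call(rbind, rows)
  meta <- lib$metadata
  if (any(!is.na(meta$location))) out$location <- meta$location
  if (any(!is.na(meta$biomass))) out$biomass <- meta$biomass
  out
}
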