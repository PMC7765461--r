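#' Evaluate the red-edge logistic segment
#'
#' Three-parameter logistic in the offset wavelength `lambda - origin`:
#' `f(x) = r680 * K / (r680 + (K - r680) * exp(-C * x))`. At the origin
#' (660 nm) the closed form reduces to `r680` exactly; for `C > 0` and
#' `K > r680` it rises monotonically towards the asymptote `K`.
#'
#' @param lambda Wavelengths, nm.
#' @param r680 Logistic start level (the red band value).
#' @param K Asymptote (the NIR band value).
#' @param C Growth rate, per nm.
#' @param origin Wavelength at which the logistic starts, nm.
#' @return Reflectance values at `lambda`.
#' @export
logistic_segment <- function(lambda, r680, K, C, origin = 660) {
  x <- lambda - origin
  r680 * K / (r680 + (K - r680) * exp(-C * x))
}

#' Fit the visible linear segment from the green and red bands
#'
#' The segment is anchored at the green band: `f(lambda) = r_start +
#' (lambda - 550) * beta` with `beta = (red - green) / (660 - 550)`, so it
#' passes through both band values exactly.
#'
#' @param green,red Band reflectance fractions at 550 and 660 nm.
#' @return List with `r_start` (reflectance at 550 nm) and `beta`
#'   (reflectance per nm).
#' @export
fit_linear <- function(green, red) {
  if (!is.finite(green) || !is.finite(red)) {
    abort_ps("green and red band values must be finite",
             "pasturespec_format_error")
  }
  list(r_start = green, beta = (red - green) / 110)
}

#' Fit the logistic growth rate C by Nelder--Mead
#'
#' The red and NIR bands fix the logistic start level (`r680 = red`) and
#' asymptote (`K = nir`); the remaining growth rate C is found by
#' Nelder--Mead (`stats::optim`) on `log C` (which keeps C positive
#' without a bounded optimizer), minimizing the sum of squared residuals
#' between the logistic evaluated at the band centers (660, 735, 790 nm)
#' and the observed band values. The residual at 660 nm is identically
#' zero by construction; the residual at 790 nm is small but structurally
#' nonzero for finite C, since a logistic only reaches its asymptote in
#' the limit.
#'
#' The optimizer is initialized at the closed-form inversion of the
#' red-edge band, `C0 = -log(r680 (K - R735) / (R735 (K - r680))) / 75`,
#' falling back to 0.02 per nm when that expression is undefined.
#'
#' @param red,red_edge,nir Band reflectance fractions. Requires
#'   `0 < red < nir` (a rising red edge); otherwise a non-sigmoid error of
#'   class `"pasturespec_non_sigmoid"` is raised.
#' @param objective `"centers"` (default) evaluates the logistic at the
#'   band centers; `"srf"` convolves the full piecewise spectrum with
#'   `sensor` and compares model bands instead.
#' @param sensor,grid Sensor model and wavelength grid, used only for
#'   `objective = "srf"` (the green band is needed to assemble the full
#'   piecewise spectrum there).
#' @param green Green band value, required for `objective = "srf"`.
#' @param init Optional starting value for C.
#' @param reltol,maxit Nelder--Mead control; the tight default tolerance
#'   lets self-consistent inputs be recovered to near machine precision.
#' @return List with `C`, `objective_value`, `converged` and `iterations`.
#' @export
fit_logistic_C <- function(red, red_edge, nir,
                           objective = c("centers", "srf"),
                           sensor = NULL, grid = wavelength_grid(),
                           green = NULL, init = NULL,
                           reltol = 1e-14, maxit = 500L) {
  objective <- match.arg(objective)
  if (!is.finite(red) || !is.finite(red_edge) || !is.finite(nir)) {
    abort_ps("band values must be finite", "pasturespec_format_error")
  }
  if (red <= 0) {
    abort_ps("red band must be positive", "pasturespec_non_sigmoid")
  }
  if (red >= nir) {
    abort_ps(sprintf(
      "red band (%.4g) >= nir band (%.4g): no rising red edge to fit",
      red, nir), "pasturespec_non_sigmoid")
  }
  if (is.null(init)) {
    arg <- red * (nir - red_edge) / (red_edge * (nir - red))
    init <- if (is.finite(arg) && arg > 0 && arg < 1) -log(arg) / 75 else 0.02
  }
  fn <- if (objective == "centers") {
    function(logc) {
      C <- exp(logc)
      (logistic_segment(735, red, nir, C) - red_edge)^2 +
        (logistic_segment(790, red, nir, C) - nir)^2
    }
  } else {
    if (is.null(sensor)) sensor <- sensor_model()
    if (is.null(green)) {
      abort_ps("objective = 'srf' needs the green band to build the spectrum",
               "pasturespec_format_error")
    }
    lin <- fit_linear(green, red)
    obs <- c(red, red_edge, nir)
    function(logc) {
      C <- exp(logc)
      vals <- piecewise_values(grid, lin$r_start, lin$beta, red, nir, C)
      s <- list(wavelengths = grid, reflectance = pmax(vals, 0), id = "fit")
      mod <- vapply(sensor$bands[c("red", "red_edge", "nir")],
                    function(b) sum(band_weights(b, grid) * s$reflectance),
                    numeric(1L))
      sum((mod - obs)^2)
    }
  }
  opt <- suppressWarnings(
    stats::optim(log(init), fn, method = "Nelder-Mead",
                 control = list(reltol = reltol, maxit = maxit)))
  if (!is.finite(opt$value)) {
    abort_ps("logistic fit did not produce a finite objective",
             "pasturespec_fit_error")
  }
  list(C = exp(opt$par[1L]), objective_value = opt$value,
       converged = opt$convergence == 0L,
       iterations = unname(opt$counts["function"]))
}

# Piecewise evaluation: linear below the breakpoint, logistic at and
# beyond it. No continuity constraint; the jump at the breakpoint is a
# documented property of the model.
piecewise_values <- function(lambda, r_start, beta, r680, K, C,
                             breakpoint = 685, origin = 660) {
  ifelse(lambda < breakpoint,
         r_start + (lambda - 550) * beta,
         logistic_segment(lambda, r680, K, C, origin))
}

#' Reconstruct a narrowband spectrum from four band values
#'
#' Assembles the piecewise model: a linear segment through the green and
#' red bands for wavelengths below the 685 nm breakpoint, and a
#' three-parameter logistic (start level = red band, asymptote = NIR band,
#' growth rate fitted by [fit_logistic_C()]) with its origin at 660 nm for
#' wavelengths at and beyond it. No continuity or differentiability
#' constraint is applied at the breakpoint: the known discontinuity is
#' preserved and its magnitude reported in the fit.
#'
#' @param bands A `"band_values"` object, a named list, or a one-row data
#'   frame with elements `green`, `red`, `red_edge`, `nir` and optionally
#'   `id`.
#' @param grid Output wavelengths, default [wavelength_grid()].
#' @param breakpoint Piecewise breakpoint, nm.
#' @param flat_fallback If `TRUE`, degenerate inputs with no rising red
#'   edge (`red >= nir`, e.g. bare soil) return a flat spectrum at the mean
#'   band value instead of raising a non-sigmoid error.
#' @param ... Passed to [fit_logistic_C()].
#' @return List with `spectrum` (a [spectrum()] on `grid`) and `fit` (a
#'   `"piecewise_fit"`: `beta`, `r_start`, `r680`, `K`, `C`, `breakpoint`,
#'   `logistic_origin`, `objective_value`, `converged`,
#'   `discontinuity_685`).
#' @export
reconstruct <- function(bands, grid = wavelength_grid(), breakpoint = 685,
                        flat_fallback = FALSE, ...) {
  b <- as_band_row(bands)
  degenerate <- is.finite(b$red) && is.finite(b$nir) &&
    (b$red >= b$nir || b$red <= 0)
  if (degenerate && flat_fallback) {
    level <- mean(c(b$green, b$red, b$red_edge, b$nir))
    fit <- structure(list(
      id = b$id, beta = 0, r_start = level, r680 = level, K = level,
      C = NA_real_, breakpoint = breakpoint, logistic_origin = 660,
      objective_value = NA_real_, converged = NA,
      discontinuity_685 = 0, flat_fallback = TRUE),
      class = "piecewise_fit")
    return(list(spectrum = spectrum(grid, rep(level, length(grid)), b$id),
                fit = fit))
  }
  lin <- fit_linear(b$green, b$red)
  lg <- fit_logistic_C(b$red, b$red_edge, b$nir, green = b$green,
                       grid = grid, ...)
  fit <- structure(list(
    id = b$id, beta = lin$beta, r_start = lin$r_start, r680 = b$red,
    K = b$nir, C = lg$C, breakpoint = breakpoint, logistic_origin = 660,
    objective_value = lg$objective_value, converged = lg$converged,
    discontinuity_685 = logistic_segment(breakpoint, b$red, b$nir, lg$C) -
      (lin$r_start + (breakpoint - 550) * lin$beta),
    flat_fallback = FALSE),
    class = "piecewise_fit")
  vals <- piecewise_values(grid, lin$r_start, lin$beta, b$red, b$nir, lg$C,
                           breakpoint = breakpoint)
  list(spectrum = spectrum(grid, pmin(pmax(vals, 0), 1.5), id = b$id),
       fit = fit)
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf(
    "<piecewise_fit> id=%s beta=%.4g r680=%.4g K=%.4g C=%.4g jump685=%.4g\n",
    x$id, x$beta, x$r680, x$K, x$C, x$discontinuity_685))
  invisible(x)
}

as_band_row <- function(bands) {
  b <- as.list(bands)
  need <- c("green", "red", "red_edge", "nir")
  if (!all(need %in% names(b))) {
    abort_ps(sprintf("band input must provide %s",
                     paste(need, collapse = ", ")),
             "pasturespec_format_error")
  }
  list(id = if (is.null(b$id)) "spec" else as.character(b$id),
       green = as.numeric(b$green), red = as.numeric(b$red),
       red_edge = as.numeric(b$red_edge), nir = as.numeric(b$nir))
}

#' Reconstruct a library of spectra from a band table
#'
#' Applies [reconstruct()] to every row, collecting per-row failures
#' (e.g. non-sigmoid rows with no rising red edge) in the fit report
#' rather than aborting the whole batch.
#'
#' @param bands Data frame with columns `green`, `red`, `red_edge`, `nir`
#'   and optionally `id`, `location`, `biomass` (metadata are carried into
#'   the reconstructed library).
#' @param grid Output wavelengths.
#' @param ... Passed to [reconstruct()].
#' @return List with `library` (a [spectral_library()] of the successful
#'   rows, input order preserved) and `report` (one row per input row:
#'   `id`, `beta`, `r_start`, `r680`, `K`, `C`, `objective`, `converged`,
#'   `discontinuity_685`, `status`, `message`).
#' @export
reconstruct_library <- function(bands, grid = wavelength_grid(), ...) {
  bands <- as.data.frame(bands, stringsAsFactors = FALSE)
  n <- nrow(bands)
  if (is.null(bands$id)) bands$id <- sprintf("s%04d", seq_len(n))
  rows <- vector("list", n)
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      reconstruct(bands[i, , drop = FALSE], grid = grid, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(
        id = as.character(bands$id[i]), beta = NA_real_, r_start = NA_real_,
        r680 = NA_real_, K = NA_real_, C = NA_real_, objective = NA_real_,
        converged = NA, discontinuity_685 = NA_real_,
        status = if (inherits(res, "pasturespec_non_sigmoid"))
          "non_sigmoid" else "error",
        message = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      f <- res$fit
      spectra[[i]] <- res$spectrum
      rows[[i]] <- data.frame(
        id = f$id, beta = f$beta, r_start = f$r_start, r680 = f$r680,
        K = f$K, C = f$C, objective = f$objective_value,
        converged = isTRUE(f$converged),
        discontinuity_685 = f$discontinuity_685,
        status = if (isTRUE(f$flat_fallback)) "flat_fallback" else "ok",
        message = "", stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  keep <- !vapply(spectra, is.null, logical(1L))
  lib <- NULL
  if (any(keep)) {
    meta <- data.frame(id = as.character(bands$id[keep]),
                       stringsAsFactors = FALSE)
    if (!is.null(bands$location)) meta$location <- bands$location[keep]
    if (!is.null(bands$biomass)) meta$biomass <- bands$biomass[keep]
    lib <- spectral_library(spectra[keep], metadata = meta)
  }
  list(library = lib, report = report)
}
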