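#' Construct a reflectance spectrum
#'
#' The atom of all spectral math in this package: a strictly increasing
#' wavelength grid (nm) paired with top-of-canopy reflectance expressed as a
#' unitless fraction. Values slightly above 1 can occur under sensor noise
#' and are accepted up to 1.5; negative values are rejected.
#'
#' @param wavelengths Numeric vector, nm, strictly increasing.
#' @param reflectance Numeric vector of reflectance fractions, same length
#'   as `wavelengths`, finite, in `[0, 1.5]`.
#' @param id Sample identifier string.
#' @return An object of class `"spectrum"`: a list with elements
#'   `wavelengths`, `reflectance` and `id`.
#' @examples
#' s <- spectrum(550:790, rep(0.3, 241), id = "flat")
#' @export
spectrum <- function(wavelengths, reflectance, id = "spec") {
  wavelengths <- as.numeric(wavelengths)
  reflectance <- as.numeric(reflectance)
  if (length(wavelengths) != length(reflectance)) {
    abort_ps("wavelengths and reflectance must have the same length",
             "pasturespec_format_error")
  }
  if (length(wavelengths) == 0L) {
    abort_ps("a spectrum needs at least one point", "pasturespec_format_error")
  }
  if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0)) {
    abort_ps("wavelengths must be finite and strictly increasing",
             "pasturespec_grid_error")
  }
  if (any(!is.finite(reflectance))) {
    abort_ps("reflectance values must be finite", "pasturespec_format_error")
  }
  if (any(reflectance < 0)) {
    i <- which(reflectance < 0)[1L]
    abort_ps(sprintf("negative reflectance (%.4g) at %g nm",
                     reflectance[i], wavelengths[i]),
             "pasturespec_format_error")
  }
  if (any(reflectance > 1.5)) {
    i <- which(reflectance > 1.5)[1L]
    abort_ps(sprintf(
      "reflectance %.4g at %g nm exceeds 1.5; percent-scale input?",
      reflectance[i], wavelengths[i]), "pasturespec_format_error")
  }
  structure(list(wavelengths = wavelengths, reflectance = reflectance,
                 id = as.character(id)),
            class = "spectrum")
}

#' Canonical reconstruction wavelength grid
#'
#' The default grid spans 550--790 nm at 1 nm step (241 points), the range
#' over which the piecewise retrieval is defined and the finest resolution
#' its features (e.g. the 745/755 nm ratio index) require.
#'
#' @param start,stop,step Grid definition in nm.
#' @return Numeric vector of wavelengths.
#' @export
wavelength_grid <- function(start = 550, stop = 790, step = 1) {
  if (!is.finite(start) || !is.finite(stop) || !is.finite(step) ||
      step <= 0 || stop <= start) {
    abort_ps("invalid wavelength grid definition", "pasturespec_grid_error")
  }
  seq(start, stop, by = step)
}

#' Bundle spectra sharing one grid into a spectral library
#'
#' @param spectra List of [spectrum()] objects, all on an identical
#'   wavelength grid, with unique ids.
#' @param metadata Optional data frame with one row per spectrum: column
#'   `id` (matching spectrum ids one-to-one) plus any of `location`
#'   (string), `biomass` (kg DM/ha, nonnegative) and `date` (ISO string).
#' @return An object of class `"spectral_library"` with elements
#'   `wavelengths`, `values` (samples x wavelengths matrix, rownames = ids)
#'   and `metadata`.
#' @export
spectral_library <- function(spectra, metadata = NULL) {
  if (!is.list(spectra)) abort_ps("spectra must be a list",
                                  "pasturespec_format_error")
  if (length(spectra) == 0L) {
    abort_ps("use new_spectral_library() for empty libraries",
             "pasturespec_format_error")
  }
  wl <- spectra[[1L]]$wavelengths
  for (s in spectra) {
    if (!inherits(s, "spectrum")) {
      abort_ps("all elements must be spectrum objects",
               "pasturespec_format_error")
    }
    if (!isTRUE(all.equal(s$wavelengths, wl, tolerance = 0))) {
      abort_ps("all spectra must share one identical wavelength grid",
               "pasturespec_grid_error")
    }
  }
  ids <- vapply(spectra, function(s) s$id, character(1L))
  if (anyDuplicated(ids)) {
    abort_ps("spectrum ids must be unique", "pasturespec_format_error")
  }
  values <- do.call(rbind, lapply(spectra, function(s) s$reflectance))
  rownames(values) <- ids
  new_spectral_library(wl, values, normalize_metadata(metadata, ids))
}

# Low-level constructor; values is an n x p matrix with rownames = ids.
new_spectral_library <- function(wavelengths, values, metadata = NULL) {
  values <- as.matrix(values)
  colnames(values) <- NULL
  metadata <- normalize_metadata(metadata, rownames(values))
  structure(list(wavelengths = as.numeric(wavelengths), values = values,
                 metadata = metadata),
            class = "spectral_library")
}

# Align optional metadata to spectrum ids; fill absent fields with NA.
normalize_metadata <- function(metadata, ids) {
  ids <- as.character(ids)
  if (is.null(metadata)) {
    n <- length(ids)
    return(data.frame(id = ids, location = rep(NA_character_, n),
                      biomass = rep(NA_real_, n),
                      date = rep(NA_character_, n),
                      stringsAsFactors = FALSE))
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (is.null(metadata$id)) {
    abort_ps("metadata must contain an 'id' column", "pasturespec_format_error")
  }
  metadata$id <- as.character(metadata$id)
  if (!setequal(metadata$id, ids) || anyDuplicated(metadata$id)) {
    abort_ps("metadata ids must match spectrum ids one-to-one",
             "pasturespec_format_error")
  }
  metadata <- metadata[match(ids, metadata$id), , drop = FALSE]
  n <- nrow(metadata)
  if (is.null(metadata$location)) {
    metadata$location <- rep(NA_character_, n)
  }
  if (is.null(metadata$biomass)) metadata$biomass <- rep(NA_real_, n)
  metadata$biomass <- as.numeric(metadata$biomass)
  if (any(metadata$biomass < 0, na.rm = TRUE)) {
    abort_ps("biomass must be nonnegative", "pasturespec_format_error")
  }
  if (is.null(metadata$date)) metadata$date <- rep(NA_character_, n)
  rownames(metadata) <- NULL
  metadata[, c("id", "location", "biomass", "date")]
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf(
    "<spectral_library> %d spectra, %d wavelengths (%g-%g nm)\n",
    nrow(x$values), length(x$wavelengths),
    min(x$wavelengths), max(x$wavelengths)))
  if (any(!is.na(x$metadata$biomass))) {
    cat(sprintf("  biomass: %.0f-%.0f kg DM/ha; locations: %s\n",
                min(x$metadata$biomass, na.rm = TRUE),
                max(x$metadata$biomass, na.rm = TRUE),
                paste(unique(stats::na.omit(x$metadata$location)),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Number of spectra in a library
#' @param lib A spectral library.
#' @export
n_spectra <- function(lib) nrow(lib$values)

#' Extract one spectrum from a library
#' @param lib A spectral library.
#' @param which Sample id (string) or integer index.
#' @return A [spectrum()] object.
#' @export
get_spectrum <- function(lib, which) {
  if (is.character(which)) {
    i <- match(which, rownames(lib$values))
    if (is.na(i)) abort_ps(sprintf("no spectrum with id '%s'", which),
                           "pasturespec_format_error")
  } else {
    i <- as.integer(which)
    if (i < 1L || i > nrow(lib$values)) {
      abort_ps("spectrum index out of range", "pasturespec_format_error")
    }
  }
  spectrum(lib$wavelengths, lib$values[i, ], id = rownames(lib$values)[i])
}

#' Read a spectral library from CSV
#'
#' Two dialects are supported. *Wide*: first column `id`, optional columns
#' `location`, `biomass_kg_dm_ha`, `date`, then one column per wavelength
#' named by its nm value. *Long*: columns `id`, `wavelength_nm`,
#' `reflectance`, plus optional per-id constant `location`,
#' `biomass_kg_dm_ha`, `date` columns.
#'
#' Reflectance is stored as a fraction in `[0, 1]`; percent-scale input is
#' auto-detected (maximum value above 1.5) and divided by 100 with a
#' message.
#'
#' @param path CSV file path.
#' @param layout `"wide"` or `"long"`.
#' @return A [spectral_library()].
#' @export
read_spectral_library <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) {
    abort_ps(sprintf("file not found: %s", path), "pasturespec_format_error")
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (layout == "wide") read_wide_library(df) else read_long_library(df)
}

meta_col_map <- c(location = "location", biomass = "biomass_kg_dm_ha",
                  date = "date")

read_wide_library <- function(df) {
  if (is.null(df$id)) {
    abort_ps("wide layout requires an 'id' column", "pasturespec_format_error")
  }
  meta_cols <- intersect(unname(meta_col_map), names(df))
  wl_cols <- setdiff(names(df), c("id", meta_cols))
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (any(is.na(wl))) {
    abort_ps(sprintf("non-numeric wavelength column header: %s",
                     wl_cols[which(is.na(wl))[1L]]),
             "pasturespec_format_error")
  }
  if (length(wl) > 1L && any(diff(wl) <= 0)) {
    abort_ps("wavelength columns are not strictly increasing",
             "pasturespec_grid_error")
  }
  values <- as.matrix(df[, wl_cols, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- as.character(df$id)
  meta <- data.frame(id = as.character(df$id), stringsAsFactors = FALSE)
  for (field in names(meta_col_map)) {
    csv_name <- meta_col_map[[field]]
    if (csv_name %in% names(df)) meta[[field]] <- df[[csv_name]]
  }
  validate_ingest_values(values, wl) |>
    new_spectral_library(wavelengths = wl, metadata = meta)
}

read_long_library <- function(df) {
  need <- c("id", "wavelength_nm", "reflectance")
  if (!all(need %in% names(df))) {
    abort_ps("long layout requires columns id, wavelength_nm, reflectance",
             "pasturespec_format_error")
  }
  if (nrow(df) == 0L) {
    return(new_spectral_library(numeric(0),
                                matrix(numeric(0), nrow = 0, ncol = 0)))
  }
  ids <- unique(as.character(df$id))
  first <- df[match(ids, as.character(df$id)), , drop = FALSE]
  chunks <- split(df, factor(as.character(df$id), levels = ids))
  wl <- as.numeric(chunks[[1L]]$wavelength_nm)
  if (any(diff(wl) <= 0)) {
    abort_ps("wavelengths are not strictly increasing within sample",
             "pasturespec_grid_error")
  }
  values <- matrix(NA_real_, nrow = length(ids), ncol = length(wl),
                   dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    ch <- chunks[[i]]
    if (nrow(ch) != length(wl) ||
        !isTRUE(all.equal(as.numeric(ch$wavelength_nm), wl, tolerance = 0))) {
      abort_ps(sprintf("sample '%s' is not on the shared wavelength grid",
                       ids[i]), "pasturespec_grid_error")
    }
    values[i, ] <- as.numeric(ch$reflectance)
  }
  meta <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (field in names(meta_col_map)) {
    csv_name <- meta_col_map[[field]]
    if (csv_name %in% names(df)) meta[[field]] <- first[[csv_name]]
  }
  validate_ingest_values(values, wl) |>
    new_spectral_library(wavelengths = wl, metadata = meta)
}

# Shared ingest checks: completeness, sign, percent auto-detection.
validate_ingest_values <- function(values, wl) {
  if (nrow(values) == 0L) return(values)
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    abort_ps(sprintf("missing/non-numeric reflectance for sample '%s' at %g nm",
                     rownames(values)[bad[1L]], wl[bad[2L]]),
             "pasturespec_format_error")
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    abort_ps(sprintf("negative reflectance for sample '%s' at %g nm",
                     rownames(values)[bad[1L]], wl[bad[2L]]),
             "pasturespec_format_error")
  }
  if (max(values) > 1.5) {
    message("reflectance maximum exceeds 1.5; interpreting values as percent ",
            "and dividing by 100")
    values <- values / 100
  }
  values
}

#' Write a spectral library to CSV
#'
#' Inverse of [read_spectral_library()]; a write/read round trip preserves
#' reflectance to better than 1e-9 absolute and metadata exactly. Missing
#' biomass is written as an empty field, never zero.
#'
#' @param lib A [spectral_library()].
#' @param path Output CSV path.
#' @param layout `"wide"` or `"long"`.
#' @export
write_spectral_library <- function(lib, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  meta <- lib$metadata
  if (layout == "wide") {
    out <- data.frame(id = meta$id, stringsAsFactors = FALSE,
                      check.names = FALSE)
    if (nrow(out) == 0L) out <- data.frame(id = character(0))
    for (field in names(meta_col_map)) {
      if (any(!is.na(meta[[field]]))) {
        out[[meta_col_map[[field]]]] <- meta[[field]]
      }
    }
    vals <- as.data.frame(lib$values, check.names = FALSE)
    colnames(vals) <- format(lib$wavelengths, trim = TRUE, scientific = FALSE)
    out <- cbind(out, vals)
  } else {
    n <- nrow(lib$values)
    p <- length(lib$wavelengths)
    out <- data.frame(
      id = rep(meta$id, each = p),
      wavelength_nm = rep(lib$wavelengths, times = n),
      reflectance = as.vector(t(lib$values)),
      stringsAsFactors = FALSE)
    for (field in names(meta_col_map)) {
      if (any(!is.na(meta[[field]]))) {
        out[[meta_col_map[[field]]]] <- rep(meta[[field]], each = p)
      }
    }
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort_ps(sprintf("cannot write to %s", path),
                    "pasturespec_format_error")
  invisible(path)
}

#' Linearly resample a spectrum onto a wavelength grid
#'
#' Linear interpolation only; requests outside the span of the source
#' spectrum raise a range error rather than extrapolating.
#'
#' @param s A [spectrum()].
#' @param grid Target wavelengths (nm), e.g. from [wavelength_grid()].
#' @return A [spectrum()] on `grid`.
#' @export
resample_to_grid <- function(s, grid) {
  grid <- as.numeric(grid)
  if (min(grid) < min(s$wavelengths) || max(grid) > max(s$wavelengths)) {
    abort_ps(sprintf(
      "grid [%g, %g] nm extends beyond spectrum span [%g, %g] nm",
      min(grid), max(grid), min(s$wavelengths), max(s$wavelengths)),
      "pasturespec_range_error")
  }
  vals <- stats::approx(s$wavelengths, s$reflectance, xout = grid,
                        method = "linear", ties = "ordered")$y
  spectrum(grid, vals, id = s$id)
}

#' Resample every spectrum of a library onto a grid
#' @param lib A [spectral_library()].
#' @param grid Target wavelengths (nm).
#' @return A [spectral_library()] on `grid`.
#' @export
resample_library <- function(lib, grid) {
  grid <- as.numeric(grid)
  if (min(grid) < min(lib$wavelengths) || max(grid) > max(lib$wavelengths)) {
    abort_ps("grid extends beyond library span", "pasturespec_range_error")
  }
  values <- t(apply(lib$values, 1L, function(r) {
    stats::approx(lib$wavelengths, r, xout = grid, method = "linear",
                  ties = "ordered")$y
  }))
  if (length(grid) == 1L) values <- matrix(values, ncol = 1L)
  rownames(values) <- rownames(lib$values)
  new_spectral_library(grid, values, lib$metadata)
}
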