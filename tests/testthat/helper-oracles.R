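# Independent oracles used to cross-check production code. Each is a
# deliberately naive implementation (dense enumeration, brute force,
# closed form) that shares no code path with the package internals.

# Dense grid search over log C for the logistic growth-rate objective:
# SSE of the logistic (start level = red at 660 nm, asymptote = nir)
# against the red-edge and NIR band values at their centers. Coarse pass
# over the full plausible range, then a fine pass of `n_fine` points
# around the coarse minimum.
oracle_grid_search_C <- function(red, red_edge, nir, lo = 1e-4, hi = 1,
                                 n_coarse = 1000, n_fine = 1e5) {
  obj <- function(C) {
    m735 <- red * nir / (red + (nir - red) * exp(-C * 75))
    m790 <- red * nir / (red + (nir - red) * exp(-C * 130))
    (m735 - red_edge)^2 + (m790 - nir)^2
  }
  g1 <- exp(seq(log(lo), log(hi), length.out = n_coarse))
  i1 <- which.min(obj(g1))
  g2 <- exp(seq(log(g1[max(1, i1 - 1)]), log(g1[min(n_coarse, i1 + 1)]),
                length.out = n_fine))
  g2[which.min(obj(g2))]
}

# Brute-force upper concave envelope: at each point the hull value is the
# maximum over all chords (i, j) with x_i <= x_k <= x_j.
oracle_brute_hull <- function(x, y) {
  n <- length(x)
  vapply(seq_len(n), function(k) {
    best <- y[k]
    for (i in seq_len(k)) {
      for (j in k:n) {
        if (x[j] > x[i]) {
          v <- y[i] + (y[j] - y[i]) * (x[k] - x[i]) / (x[j] - x[i])
          if (v > best) best <- v
        }
      }
    }
    best
  }, numeric(1))
}

# Band value by quadrature of an interpolated spectrum on a much finer
# grid than the native one (independent check of the discrete SRF
# renormalization).
oracle_dense_band_value <- function(wavelengths, reflectance, center,
                                    width, step = 0.1) {
  lo <- max(center - width / 2, min(wavelengths))
  hi <- min(center + width / 2, max(wavelengths))
  fine <- seq(lo, hi, by = step)
  vals <- stats::approx(wavelengths, reflectance, xout = fine)$y
  w <- rep(1, length(fine))
  w[c(1, length(fine))] <- 0.5
  sum(w * vals) / sum(w)
}

# Exact piecewise curve from generating parameters (mirrors the model
# definition arithmetically, independent of package internals).
oracle_piecewise_curve <- function(grid, r550, beta, r680, K, C) {
  ifelse(grid < 685,
         r550 + (grid - 550) * beta,
         r680 * K / (r680 + (K - r680) * exp(-C * (grid - 660))))
}

# Small random spectral library for round-trip property tests.
random_library <- function(n = 3, seed = 1, with_meta = TRUE) {
  set.seed(seed)
  grid <- wavelength_grid()
  spectra <- lapply(seq_len(n), function(i) {
    spectrum(grid, pmin(pmax(stats::runif(1, 0.05, 0.4) +
      cumsum(stats::rnorm(length(grid), 0, 0.002)), 0), 1),
      id = sprintf("r%03d", i))
  })
  meta <- if (with_meta) {
    data.frame(id = sprintf("r%03d", seq_len(n)),
               location = sample(c("A", "B"), n, replace = TRUE),
               biomass = round(stats::runif(n, 100, 4000), 1),
               stringsAsFactors = FALSE)
  } else NULL
  spectral_library(spectra, metadata = meta)
}
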