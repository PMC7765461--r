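# Internal helpers shared across modules.

# Structured error so callers can branch on failure class.
abort_ps <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pasturespec_error")))
}

# Index of the grid point nearest to a target wavelength.
nearest_index <- function(wavelengths, lambda) {
  which.min(abs(wavelengths - lambda))
}

# Trapezoid integral of y over x (x strictly increasing).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# Per-point trapezoid quadrature weights: integrating sum(w * y) over the
# grid equals trapz(x, y).
trapezoid_weights <- function(x) {
  n <- length(x)
  if (n == 1L) return(1)
  w <- numeric(n)
  w[1L] <- (x[2L] - x[1L]) / 2
  w[n] <- (x[n] - x[n - 1L]) / 2
  if (n > 2L) w[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  w
}

rmse <- function(observed, predicted) {
  sqrt(mean((observed - predicted)^2))
}

# Squared Pearson correlation, the R^2 convention of the modelling
# workflow this package mirrors. NA when either side is constant.
rsq <- function(observed, predicted) {
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) return(NA_real_)
  stats::cor(observed, predicted)^2
}
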