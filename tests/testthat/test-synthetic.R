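test_that("identical configs generate identical libraries", {
  cfg <- generator_config(n = 50, seed = 99, narrowband = TRUE)
  l1 <- generate_library(cfg)
  l2 <- generate_library(cfg)
  expect_identical(l1$values, l2$values)
  expect_identical(l1$metadata, l2$metadata)
  expect_identical(attr(l1, "truth"), attr(l2, "truth"))
  # and a different seed does not
  l3 <- generate_library(generator_config(n = 50, seed = 100,
                                          narrowband = TRUE))
  expect_false(identical(l1$values, l3$values))
})

test_that("noiseless spectra equal the exact piecewise curve of their
          ground-truth parameters", {
  cfg <- generator_config(n = 40, noise_sd = 0, narrowband = FALSE,
                          seed = 12)
  lib <- generate_library(cfg)
  tr <- attr(lib, "truth")
  grid <- lib$wavelengths
  for (i in seq_len(40)) {
    curve <- oracle_piecewise_curve(grid, tr$r550[i], tr$beta[i],
                                    tr$r680[i], tr$K[i], tr$C[i])
    expect_lt(max(abs(lib$values[i, ] - pmin(pmax(curve, 0.001), 1))),
              1e-12)
    # the linear segment meets the logistic start level at 660 nm
    expect_equal(unname(lib$values[i, grid == 660]), tr$r680[i],
                 tolerance = 1e-12)
  }
  # reflectance respects the configured clip range
  expect_true(all(lib$values >= 0.001 & lib$values <= 1))
})

test_that("delta-sampled bands of a noiseless library equal the curve at
          band centers", {
  cfg <- generator_config(n = 30, noise_sd = 0, narrowband = FALSE,
                          seed = 14)
  lib <- generate_library(cfg)
  bt <- band_table(lib, sensor_model(shape = "delta"))
  grid <- lib$wavelengths
  expect_equal(bt$green, unname(lib$values[, grid == 550]),
               tolerance = 1e-12)
  expect_equal(bt$red, unname(lib$values[, grid == 660]),
               tolerance = 1e-12)
  expect_equal(bt$red_edge, unname(lib$values[, grid == 735]),
               tolerance = 1e-12)
  expect_equal(bt$nir, unname(lib$values[, grid == 790]),
               tolerance = 1e-12)
  # boxcar differs from delta most where the spectrum is curved or the
  # band support is clipped at a grid edge (green, nir); the red band
  # averages a linear segment symmetrically, so it matches delta exactly
  bb <- band_table(lib, sensor_model())
  expect_lt(mean(abs(bb$red - bt$red)), 1e-12)
  expect_gt(mean(abs(bb$nir - bt$nir)), mean(abs(bb$red_edge - bt$red_edge)))
})

test_that("fitted growth rates track the generating ground truth on
          noiseless data", {
  cfg <- generator_config(n = 100, noise_sd = 0, narrowband = FALSE,
                          seed = 5)
  lib <- generate_library(cfg)
  tr <- attr(lib, "truth")
  res <- reconstruct_library(band_table(lib, sensor_model(shape = "delta")))
  expect_true(all(res$report$status == "ok"))
  # the NIR band sits slightly below the logistic asymptote at finite
  # steepness, so the refit is a close but not exact recovery
  expect_gt(stats::cor(res$report$C, tr$C), 0.99)
  expect_lt(stats::median(abs(res$report$C - tr$C) / tr$C), 0.05)
})

test_that("biomass draws follow the configured distribution and location
          shifts propagate", {
  cfg <- generator_config(n = 2000, seed = 8)
  b <- generate_library(cfg)$metadata$biomass
  ks <- suppressWarnings(stats::ks.test(b, "punif", 100, 4000))
  expect_lt(unname(ks$statistic), 0.05)
  # a configured between-location biomass shift is recovered within two
  # standard errors of the difference in means
  locs <- data.frame(label = c("lo", "hi"), biomass_shift = c(0, 400))
  m <- generate_library(generator_config(n = 2000, seed = 10,
                                         locations = locs))$metadata
  mu <- tapply(m$biomass, m$location, mean)
  nn <- table(m$location)
  se <- stats::sd(b) * sqrt(sum(1 / nn))
  expect_lt(abs((mu[["hi"]] - mu[["lo"]]) - 400), 2 * se)
})

test_that("band-value NDVI saturates above the configured scale", {
  cfg <- generator_config(n = 500, biomass_range = c(100, 6000),
                          noise_sd = 0.005, seed = 4)
  bt <- generate_band_table(cfg)
  ndvi <- compute_vi(bt, "ndvi")
  low <- bt$biomass < 1500
  high <- bt$biomass > 4500
  expect_gt(stats::cor(ndvi[low], bt$biomass[low], method = "spearman"),
            0.9)
  expect_lt(abs(stats::cor(ndvi[high], bt$biomass[high],
                           method = "spearman")), 0.5)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(biomass_range = c(4000, 100)),
               class = "pasturespec_config_error")
  expect_error(generator_config(n = 0), class = "pasturespec_config_error")
  expect_error(generator_config(noise_sd = -1),
               class = "pasturespec_config_error")
})
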