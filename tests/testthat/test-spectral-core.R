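test_that("spectrum constructor enforces its invariants", {
  s <- spectrum(550:560, seq(0.1, 0.2, length.out = 11), id = "a")
  expect_s3_class(s, "spectrum")
  expect_error(spectrum(c(550, 550, 551), c(1, 1, 1)),
               class = "pasturespec_grid_error")
  expect_error(spectrum(550:552, c(0.1, -0.01, 0.1)),
               regexp = "negative")
  expect_error(spectrum(550:552, c(0.1, 2.0, 0.1)),
               regexp = "exceeds 1.5")
  expect_error(spectrum(550:552, c(0.1, NA, 0.1)),
               class = "pasturespec_format_error")
})

test_that("wide and long CSV layouts read to identical libraries", {
  lib <- random_library(n = 2, seed = 3)
  wide <- tempfile(fileext = ".csv")
  long <- tempfile(fileext = ".csv")
  write_spectral_library(lib, wide, layout = "wide")
  write_spectral_library(lib, long, layout = "long")
  lw <- read_spectral_library(wide, layout = "wide")
  ll <- read_spectral_library(long, layout = "long")
  expect_equal(lw$values, ll$values, tolerance = 1e-12)
  expect_identical(lw$metadata, ll$metadata)
  expect_identical(length(lw$wavelengths), 241L)
  unlink(c(wide, long))
})

test_that("read/write round trip preserves values and metadata", {
  for (seed in 1:5) {
    lib <- random_library(n = 1 + seed %% 4, seed = seed,
                          with_meta = seed %% 2 == 0)
    path <- tempfile(fileext = ".csv")
    write_spectral_library(lib, path)
    back <- read_spectral_library(path)
    expect_lt(max(abs(back$values - lib$values)), 1e-9)
    expect_identical(back$metadata$id, lib$metadata$id)
    expect_equal(back$metadata$biomass, lib$metadata$biomass,
                 tolerance = 1e-9)
    unlink(path)
  }
})

test_that("missing biomass survives a round trip as missing, not zero", {
  lib <- random_library(n = 3, seed = 9)
  lib$metadata$biomass[2] <- NA_real_
  path <- tempfile(fileext = ".csv")
  write_spectral_library(lib, path)
  txt <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character")
  expect_identical(txt$biomass_kg_dm_ha[2], "")
  back <- read_spectral_library(path)
  expect_true(is.na(back$metadata$biomass[2]))
  expect_false(any(back$metadata$biomass[c(1, 3)] == 0))
  unlink(path)
})

test_that("ingest rejects negative reflectance naming row and wavelength", {
  lib <- random_library(n = 2, seed = 5)
  path <- tempfile(fileext = ".csv")
  write_spectral_library(lib, path)
  df <- utils::read.csv(path, check.names = FALSE)
  df[2, "600"] <- -0.05
  utils::write.csv(df, path, row.names = FALSE, na = "")
  expect_error(read_spectral_library(path), regexp = "r002.*600")
  unlink(path)
})

test_that("percent-scale reflectance is auto-detected and rescaled", {
  grid <- wavelength_grid()
  lib <- spectral_library(list(spectrum(grid, rep(0.42, 241), id = "p1")))
  path <- tempfile(fileext = ".csv")
  write_spectral_library(lib, path)
  df <- utils::read.csv(path, check.names = FALSE)
  df[, -1] <- df[, -1] * 100
  utils::write.csv(df, path, row.names = FALSE, na = "")
  expect_message(back <- read_spectral_library(path), regexp = "percent")
  expect_equal(unname(back$values[1, 1]), 0.42, tolerance = 1e-12)
  unlink(path)
})

test_that("empty library writes a header-only file that reads back empty", {
  lib <- pasturespec:::new_spectral_library(
    wavelength_grid(), matrix(numeric(0), nrow = 0, ncol = 241))
  path <- tempfile(fileext = ".csv")
  write_spectral_library(lib, path, layout = "long")
  back <- read_spectral_library(path, layout = "long")
  expect_identical(nrow(back$values), 0L)
  unlink(path)
})

test_that("resampling is exact on linear data and idempotent", {
  grid <- wavelength_grid()
  ramp <- spectrum(grid, 0.001 * (grid - 550), id = "ramp")
  sub <- wavelength_grid(560, 780, 2.5)
  res <- resample_to_grid(ramp, sub)
  expect_equal(res$reflectance, 0.001 * (sub - 550), tolerance = 1e-12)
  # identity on own grid
  expect_equal(resample_to_grid(ramp, grid)$reflectance, ramp$reflectance)
  # idempotence
  twice <- resample_to_grid(res, sub)
  expect_identical(twice$reflectance, res$reflectance)
  # extrapolation refused
  expect_error(resample_to_grid(ramp, wavelength_grid(540, 790, 1)),
               class = "pasturespec_range_error")
})
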