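test_that("the V-shaped toy spectrum is continuum-removed by hand values", {
  # wavelengths only need to be increasing; use unit spacing
  s <- spectrum(0:2 + 550, c(1.0, 0.5, 1.0), id = "v")
  cres <- continuum_remove(s)
  expect_equal(cres$hull, c(1, 1, 1), tolerance = 1e-15)
  expect_equal(cres$cr, c(1, 0.5, 1), tolerance = 1e-15)
  expect_equal(cres$band_depth, c(0, 0.5, 0), tolerance = 1e-15)
  expect_equal(cres$Dc, 0.5, tolerance = 1e-15)
  expect_identical(cres$max_depth_position, 551)
  expect_equal(cres$band_area, 0.5, tolerance = 1e-15)
  # NBDI at the maximum-depth position is 0 by construction
  expect_identical(nbdi(cres, 551), 0)
  # and -1 where the band depth vanishes
  expect_identical(nbdi(cres, 550), -1)
})

test_that("a linear spectrum has zero band depth everywhere", {
  grid <- wavelength_grid()
  s <- spectrum(grid, 0.1 + 0.002 * (grid - 550))
  cres <- continuum_remove(s)
  expect_equal(cres$hull, s$reflectance, tolerance = 1e-12)
  expect_true(all(cres$band_depth < 1e-12))
  expect_equal(cres$band_area, 0, tolerance = 1e-9)
})

test_that("production hull equals the brute-force chord maximum", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(5:50, 1)
    x <- sort(stats::runif(n, 0, 100))
    x <- x + seq_len(n) * 1e-6  # guarantee strict increase
    y <- stats::runif(n, 0.05, 1)
    s <- spectrum(x + 550, y)
    cres <- continuum_remove(s)
    hull_o <- oracle_brute_hull(x, y)
    expect_lt(max(abs(cres$hull - hull_o)), 1e-12)
    expect_lt(max(abs(cres$band_depth - (1 - y / hull_o))), 1e-12)
  }
})

test_that("hull endpoints touch the spectrum and the hull is concave", {
  set.seed(4)
  grid <- wavelength_grid()
  r <- pmin(pmax(0.3 + cumsum(stats::rnorm(241, 0, 0.004)), 0.01), 1)
  cres <- continuum_remove(spectrum(grid, r))
  expect_equal(cres$cr[1], 1, tolerance = 1e-15)
  expect_equal(cres$cr[241], 1, tolerance = 1e-15)
  expect_true(all(cres$hull >= r - 1e-12))
  expect_true(all(diff(diff(cres$hull)) < 1e-9))  # concave
})

test_that("continuum removal is invariant to positive scaling", {
  set.seed(8)
  grid <- wavelength_grid()
  r <- pmin(pmax(0.2 + cumsum(stats::rnorm(241, 0, 0.003)), 0.01), 0.7)
  c1 <- continuum_remove(spectrum(grid, r))
  c2 <- continuum_remove(spectrum(grid, r * 2))
  expect_equal(c1$cr, c2$cr, tolerance = 1e-12)
  expect_equal(c1$band_depth, c2$band_depth, tolerance = 1e-12)
  expect_equal(c1$band_area, c2$band_area, tolerance = 1e-10)
})

test_that("NBDI stays in [-1, 0] and matches direct arithmetic", {
  # BD = 0.25 with Dc = 0.5 -> (0.25 - 0.5) / 0.75 = -1/3
  s <- spectrum(550:554, c(1, 0.75, 0.5, 0.75, 1))
  cres <- continuum_remove(s)
  expect_equal(nbdi(cres, 551), (0.25 - 0.5) / 0.75, tolerance = 1e-12)
  set.seed(13)
  for (i in 1:50) {
    r <- pmin(pmax(0.3 + cumsum(stats::rnorm(50, 0, 0.01)), 0.01), 1)
    cres <- continuum_remove(spectrum(550:599, r))
    if (cres$Dc > 0) {
      vals <- vapply(seq(550, 599, 7), function(l) nbdi(cres, l), numeric(1))
      expect_true(all(vals >= -1 - 1e-12 & vals <= 1e-12))
    }
  }
})

test_that("normalized ratio index is antisymmetric and exact", {
  grid <- wavelength_grid()
  r <- rep(0.3, 241)
  r[grid == 745] <- 0.30
  r[grid == 755] <- 0.35
  s <- spectrum(grid, r)
  expect_equal(normalized_ratio_index(s, 745, 755), -0.05 / 0.65,
               tolerance = 1e-12)
  expect_equal(normalized_ratio_index(s, 755, 745), 0.05 / 0.65,
               tolerance = 1e-12)
  expect_identical(normalized_ratio_index(s, 745, 745), 0)
})

test_that("proposed feature rows are complete, deterministic and cubic-consistent", {
  bt <- generate_band_table(generator_config(n = 5, seed = 2))
  res <- reconstruct_library(bt)
  feats <- proposed_feature_table(res$library, res$report)
  expect_identical(nrow(feats), 5L)
  expect_named(feats, c("id", "band_area", "band_area_cubed",
                        "max_depth_position_cubed", "nbdi_556", "nbdi_744",
                        "optimized_nri", "C", "beta", "location", "biomass"))
  num <- vapply(feats, is.numeric, logical(1))
  expect_true(all(is.finite(as.matrix(feats[, num]))))
  expect_equal(feats$band_area_cubed, feats$band_area^3, tolerance = 1e-12)
  s1 <- get_spectrum(res$library, 1)
  f1 <- proposed_features(s1, res$report[1, ])
  f2 <- proposed_features(s1, res$report[1, ])
  expect_identical(f1, f2)
})
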