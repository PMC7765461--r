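grid <- wavelength_grid()

test_that("the linear segment passes through both anchor bands", {
  f <- fit_linear(0.05, 0.04)
  expect_equal(f$beta, -0.01 / 110, tolerance = 1e-15)
  expect_equal(f$r_start + (660 - 550) * f$beta, 0.04, tolerance = 1e-15)
  # flat case
  f0 <- fit_linear(0.05, 0.05)
  expect_identical(f0$beta, 0)
  # extrapolation past 660 up to the breakpoint
  f2 <- fit_linear(0.06, 0.03)
  expect_equal(f2$r_start + (685 - 550) * f2$beta, 0.0231818,
               tolerance = 1e-6)
})

test_that("the logistic segment honors its closed-form anchors", {
  # at the origin the closed form reduces to r680 exactly
  expect_identical(logistic_segment(660, 0.05, 0.5, 0.03), 0.05)
  # C -> 0 limit: flat at r680
  expect_equal(logistic_segment(seq(660, 790, 10), 0.05, 0.5, 1e-14),
               rep(0.05, 14), tolerance = 1e-9)
  # strictly increasing when C > 0 and K > r680
  v <- logistic_segment(685:790, 0.05, 0.5, 0.03)
  expect_true(all(diff(v) > 0))
})

test_that("Nelder-Mead growth rate matches the dense grid-search oracle", {
  # spec'd forward-evaluation example: red edge on an exact logistic
  re <- 0.05 * 0.5 / (0.05 + 0.45 * exp(-0.03 * 75))
  expect_equal(re, 0.2565954, tolerance = 1e-6)
  fit <- fit_logistic_C(0.05, re, 0.5)
  oracle <- oracle_grid_search_C(0.05, re, 0.5)
  # the NIR residual (logistic below its asymptote at 790 nm) pulls the
  # SSE minimizer above the generating 0.03; both routes must agree on it
  expect_equal(oracle, 0.0336052, tolerance = 1e-5)
  expect_lt(abs(fit$C - oracle) / oracle, 1e-5)
  # random band rows drawn from the generator
  bt <- generate_band_table(generator_config(n = 25, seed = 3))
  for (i in seq_len(nrow(bt))) {
    fit <- fit_logistic_C(bt$red[i], bt$red_edge[i], bt$nir[i])
    oracle <- oracle_grid_search_C(bt$red[i], bt$red_edge[i], bt$nir[i])
    expect_lt(abs(fit$C - oracle) / oracle, 1e-5)
  }
})

test_that("C is recovered exactly when the red edge saturates by 790 nm", {
  # with the plateau effectively reached at the NIR band, the band triple
  # (r680, logistic(735), K) is self-consistent and the single-band
  # closed form, the optimizer and the truth all coincide
  set.seed(11)
  for (i in 1:50) {
    r680 <- stats::runif(1, 0.02, 0.15)
    K <- stats::runif(1, 0.25, 1)
    C <- stats::runif(1, 0.13, 0.3)
    re <- logistic_segment(735, r680, K, C)
    fit <- fit_logistic_C(r680, re, K)
    expect_lt(abs(fit$C - C), 1e-6)
    closed <- -log(r680 * (K - re) / (re * (K - r680))) / 75
    expect_lt(abs(closed - C), 1e-8)
  }
})

test_that("degenerate band rows are refused or flattened on request", {
  flat <- list(green = 0.3, red = 0.3, red_edge = 0.3, nir = 0.3)
  expect_error(reconstruct(flat), class = "pasturespec_non_sigmoid")
  res <- reconstruct(flat, flat_fallback = TRUE)
  expect_equal(res$spectrum$reflectance, rep(0.3, 241), tolerance = 1e-12)
  expect_true(res$fit$flat_fallback)
})

test_that("reconstruction hits its anchor points and reports the jump", {
  b <- list(green = 0.08, red = 0.05, red_edge = 0.25, nir = 0.45,
            id = "anchor")
  res <- reconstruct(b)
  s <- res$spectrum
  expect_equal(s$reflectance[s$wavelengths == 550], 0.08, tolerance = 1e-12)
  # the linear segment passes through the red band at 660
  expect_equal(s$reflectance[s$wavelengths == 660], 0.05, tolerance = 1e-12)
  # below the breakpoint the spectrum is linear; at and beyond, logistic
  lin_part <- s$reflectance[s$wavelengths < 685]
  expect_equal(diff(lin_part), rep(res$fit$beta, length(lin_part) - 1),
               tolerance = 1e-12)
  expect_equal(res$fit$discontinuity_685,
               logistic_segment(685, 0.05, 0.45, res$fit$C) -
                 (0.08 + 135 * res$fit$beta),
               tolerance = 1e-12)
})

test_that("reconstruct_library isolates failures and is order-equivariant", {
  bt <- generate_band_table(generator_config(n = 10, seed = 5))
  bad <- bt
  bad$nir[4] <- bad$red[4] / 2  # kill the red edge of one row
  res <- reconstruct_library(bad)
  expect_identical(nrow(res$report), 10L)
  expect_identical(res$report$status[4], "non_sigmoid")
  expect_identical(sum(res$report$status == "ok"), 9L)
  expect_identical(n_spectra(res$library), 9L)
  # permuting rows permutes outputs identically
  perm <- c(3, 1, 2, 8, 10, 9, 4, 6, 5, 7)
  res_p <- reconstruct_library(bad[perm, ], grid)
  expect_identical(res_p$report$id, res$report$id[perm])
  expect_equal(res_p$report$C, res$report$C[perm], tolerance = 1e-12)
})
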