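test_that("sphere absorbed fraction is bounded, monotone in mass and reproducible", {
  sp <- spectrum_fixture
  afs <- vapply(c(0.001, 1, 100), function(m)
    sphere_photon_af(m, sp, histories = 2e4, seed = 1)$af, numeric(1))
  expect_true(all(afs > 0 & afs < 1))
  expect_true(all(diff(afs) > 0))
  again <- sphere_photon_af(1, sp, histories = 2e4, seed = 1)$af
  expect_identical(afs[2], again)
  expect_error(sphere_photon_af(1, sp, histories = 100), "1e4")
  expect_error(sphere_phantom(0), "> 0")
})

test_that("Monte Carlo standard error scales as histories^(-1/2)", {
  sp <- spectrum_fixture
  a <- sphere_photon_af(1, sp, histories = 1e4, seed = 5)
  b <- sphere_photon_af(1, sp, histories = 9e4, seed = 5)
  expect_equal(a$se / b$se, 3, tolerance = 0.25)
})

test_that("optically thin spheres agree with the first-flight oracle", {
  # single-line mode on a tiny sphere; the oracle is mu_en times the mean
  # path to the surface for a uniform interior isotropic source (3r/4)
  sp <- spectrum_fixture
  m <- 2e-4
  r <- sphere_phantom(m)$radius_cm
  mc <- sphere_photon_af(m, sp, histories = 2e5, seed = 2,
                         energy_model = "single")
  oracle <- photon_coefficients(sp$photon_kev_per_decay)$mu_en * 0.75 * r
  expect_lt(abs(mc$af - oracle) / oracle, 0.10)
})

test_that("power-law fit recovers exact data and rejects degenerate input", {
  m <- exp(seq(log(0.001), log(100), length.out = 10))
  fit <- fit_power_law(m, 5 * m^0.3)
  expect_equal(fit$a, 5, tolerance = 1e-9)
  expect_equal(fit$b, 0.3, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_error(fit_power_law(1, 5), ">= 3")
  expect_error(fit_power_law(c(1, 2, 3), c(-1, 2, 3)), "positive")
})

test_that("power-law evaluation reproduces the printed tumor absorbed fractions", {
  fit <- list(a = 7.2, b = 0.254)
  expect_equal(eval_power_law(fit, 1), 7.2)
  expect_equal(eval_power_law(fit, 0.001), 1.246, tolerance = 1e-3)
  expect_error(eval_power_law(fit, 0), "> 0")
})

test_that("kidney absorbed fraction is consistent with the equal-mass sphere", {
  sp <- spectrum_fixture
  k <- kidney_photon_af(0.298, sp, histories = 5e4, seed = 3)
  s <- sphere_photon_af(0.298, sp, histories = 5e4, seed = 3)
  expect_true(k$af > 0 && k$af < 1)
  # shape effect is second-order at this size
  expect_lt(abs(k$af - s$af) / s$af, 0.25)
  k10 <- kidney_photon_af(2.98, sp, histories = 5e4, seed = 3)
  expect_gt(k10$af, k$af)
  expect_identical(k$geometry, "ellipsoid")
  expect_identical(kidney_photon_af(0.298, sp, histories = 1e4, seed = 1,
                                    geometry = "sphere")$geometry, "sphere")
})

test_that("the absorbed-fraction curve is well fit by a power law", {
  sp <- spectrum_fixture
  curve <- photon_af_curve(exp(seq(log(0.001), log(100), length.out = 8)),
                           sp, histories = 2e4, seed = 11)
  expect_gte(curve$fit$r2, 0.95)
  expect_true(curve$fit$b > 0 && curve$fit$b < 1)
  expect_true(all(curve$table$af_pct > 0 & curve$table$af_pct < 100))
})
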