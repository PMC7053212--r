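test_that("nuclear volume fraction follows the cube law", {
  expect_equal(nuclear_volume_fraction(cell_geometry(26, 18)), (18 / 26)^3)
  expect_equal(round(nuclear_volume_fraction(cell_geometry(26, 18)), 2), 0.33)
  expect_equal(nuclear_volume_fraction(cell_geometry(20, 19.9999)), 1,
               tolerance = 1e-4)
  expect_equal(nuclear_volume_fraction(cell_geometry(20, 10)), 0.125)
  expect_error(cell_geometry(20, 25), "nucleus")
})

test_that("deposition fractions preserve the compartment ordering", {
  dep <- cell_deposition_fractions(histories = 3e4, seed = 2)
  phi <- setNames(dep$fractions$phi, dep$fractions$compartment)
  expect_gt(phi["perinuclear"], phi["cytoplasm"])
  expect_gt(phi["cytoplasm"], phi["membrane"])
  expect_true(all(phi >= 0 & phi <= 1))
})

test_that("point-kernel and Monte Carlo backends agree within 10%", {
  for (cp in c("perinuclear", "membrane", "cytoplasm")) {
    pk <- compartment_energy_fraction(cell_geometry(), cp,
                                      backend = "point_kernel")
    mc <- compartment_energy_fraction(cell_geometry(), cp, backend = "mc",
                                      histories = 5e4, seed = 4)
    expect_lt(abs(pk$phi - mc$phi) / pk$phi, 0.10)
    expect_identical(pk$se, 0)
    expect_gt(mc$se, 0)
  }
  expect_error(compartment_energy_fraction(cell_geometry(), "mitochondria"),
               "should be one of")
})

test_that("a nucleus much larger than the electron range contains nearly all energy", {
  big <- cell_geometry(cell_um = 500, nucleus_um = 498)
  phi <- compartment_energy_fraction(big, "nucleus", backend = "mc",
                                     histories = 2e4, seed = 6)$phi
  expect_gt(phi, 0.95)
})

test_that("energy is conserved per history across nucleus/cytoplasm/outside", {
  g <- cell_geometry()
  set.seed(9)
  E0 <- sample(spectrum_fixture$electron_lines$energy_kev, 500, replace = TRUE)
  rs <- runif(500, 9, 13)
  mu <- runif(500, -1, 1)
  fr <- augerdose:::.cell_track_fractions(E0, rs, mu, g)
  expect_equal(fr$nucleus + fr$cytoplasm + fr$outside, rep(1, 500),
               tolerance = 1e-9)
  expect_true(all(fr$nucleus >= -1e-12 & fr$cytoplasm >= -1e-12 &
                    fr$outside >= -1e-12))
})

test_that("nuclear dose ratio combines sources, deposition and nuclear mass", {
  dist <- source_distribution()
  phi <- c(perinuclear = 0.38, membrane = 0.05, cytoplasm = 0.08)
  expect_equal(nuclear_dose_ratio(dist, phi, 0.33), 0.347, tolerance = 1e-3)
  # homogeneous deposition: phi equal to the nuclear mass fraction gives 1
  hom <- c(perinuclear = 0.33, membrane = 0.33, cytoplasm = 0.33)
  expect_equal(nuclear_dose_ratio(dist, hom, 0.33), 1, tolerance = 1e-12)
  all_peri <- source_distribution(1, 0, 0)
  expect_equal(nuclear_dose_ratio(all_peri, phi, 0.33), 0.38 / 0.33,
               tolerance = 1e-12)
  expect_error(nuclear_dose_ratio(dist, phi, 0), "w_nuc")
  expect_error(source_distribution(0.5, 0.2, 0.2), "sum to 1")
})

test_that("tumor nuclear dose is the coefficient x activity x ratio", {
  expect_equal(tumor_nuclear_dose(2.6, 111, 0.347), 100.1, tolerance = 1e-3)
  expect_identical(tumor_nuclear_dose(2.6, 0, 0.35), 0)
  expect_equal(tumor_nuclear_dose(2.6, 111, 1), 288.6)
  expect_error(tumor_nuclear_dose(-1, 111, 0.3), ">= 0")
})
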