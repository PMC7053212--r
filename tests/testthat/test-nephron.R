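test_that("nephron geometry derives packing fractions and validates inputs", {
  g <- nephron_geometry()
  v_nuc <- 4 / 3 * pi * 2.5^3
  expect_equal(g$band_packing, v_nuc / (14^2 * 5))
  expect_equal(g$wall_nuclear_fraction, v_nuc / (14^2 * 10))
  expect_equal(g$band_in, 17.5)
  expect_equal(g$band_out, 22.5)
  expect_error(nephron_geometry(wall_um = -1), "> 0")
  expect_error(nephron_geometry(nucleus_um = 12), "wall")
  expect_error(nephron_geometry(occupancy = 1.4), "occupancy")
})

test_that("tubule energy partition conserves energy and orders the sources", {
  surf <- tubule_source_fractions(source = "surface", histories = 5e4,
                                  seed = 3)
  cyto <- tubule_source_fractions(source = "cytoplasm", histories = 5e4,
                                  seed = 3)
  expect_equal(sum(surf$fractions), 1, tolerance = 0.005)
  expect_equal(sum(cyto$fractions), 1, tolerance = 0.005)
  expect_true(all(surf$fractions >= 0))
  # apical-surface binding spares the nucleus relative to internalization:
  # the central normal-tissue-sparing mechanism, stated geometrically
  expect_lt(surf$fractions[["nucleus"]], cyto$fractions[["nucleus"]])
  # surface decays lose roughly half their energy to the lumen
  expect_gt(surf$fractions[["lumen"]], cyto$fractions[["lumen"]])
})

test_that("packing-average and explicit-sphere nucleus treatments agree", {
  pk <- tubule_source_fractions(source = "surface", histories = 5e4, seed = 4,
                                nucleus_mode = "packing")
  ex <- tubule_source_fractions(source = "surface", histories = 5e4, seed = 4,
                                nucleus_mode = "explicit")
  expect_lt(abs(pk$fractions[["nucleus"]] - ex$fractions[["nucleus"]]) /
              pk$fractions[["nucleus"]], 0.15)
})

test_that("proximal-tubule nuclear dose reproduces the published rescaling", {
  g <- nephron_geometry()
  # printed inputs: 0.71 Gy/MBq kidney coefficient, 111 MBq, 0.8% nuclear
  # energy fraction for surface binding
  d <- proximal_tubule_nuclei_dose(0.71, 111, 0.008, g)
  expect_equal(d$dose_gy, 0.71 * 111 * 0.43 * 0.008 / 0.134,
               tolerance = 1e-9)
  expect_equal(d$dose_gy, 2, tolerance = 0.15)
  expect_identical(proximal_tubule_nuclei_dose(0.71, 0, 0.008, g)$dose_gy, 0)
  # full internalization exposes the nuclei more than surface binding
  surf <- tubule_source_fractions(source = "surface", histories = 3e4, seed = 5)
  cyto <- tubule_source_fractions(source = "cytoplasm", histories = 3e4, seed = 5)
  expect_gt(proximal_tubule_nuclei_dose(0.71, 111, cyto, g)$dose_gy,
            proximal_tubule_nuclei_dose(0.71, 111, surf, g)$dose_gy)
  expect_named(d$provenance, c("kidney_dose_gy", "occupancy", "phi_nucleus",
                               "kidney_nuclear_mass_fraction"))
})

test_that("glomerular dose is the photon channel passthrough", {
  expect_identical(glomerular_dose(7), 7)
  expect_identical(glomerular_dose(0), 0)
})

test_that("striated-duct worst case scales reciprocally with mass fraction", {
  expect_equal(uniform_duct_dose(1.3 / 111, 111, 1 / 20), 26, tolerance = 1e-9)
  expect_equal(uniform_duct_dose(0.012, 111, 1), 1.332, tolerance = 1e-9)
  expect_equal(uniform_duct_dose(0.012, 111, 0.05),
               2 * uniform_duct_dose(0.012, 111, 0.10), tolerance = 1e-12)
  expect_error(uniform_duct_dose(0.012, 111, 0), "mass fraction")
})
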