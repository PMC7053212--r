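test_that("zero noise reproduces the kinetic means exactly and seeds reproduce", {
  m <- kinetic_model("toy", 0, c(20, 5), c(0.05, 0.002), cv = 0)
  gen <- generate_biodistribution(m, spectrum_fixture, seed = 1)
  expect_equal(gen$series$toy$samples$pct_id_per_g,
               kinetic_mean(m, m$schedule_h), tolerance = 1e-12)
  m2 <- kinetic_model("toy", 0, c(20, 5), c(0.05, 0.002), cv = 0.3)
  g1 <- generate_biodistribution(m2, spectrum_fixture, seed = 42)
  g2 <- generate_biodistribution(m2, spectrum_fixture, seed = 42)
  expect_identical(g1$series$toy$samples, g2$series$toy$samples)
  g3 <- generate_biodistribution(m2, spectrum_fixture, seed = 43)
  expect_false(identical(g1$series$toy$samples$pct_id_per_g,
                         g3$series$toy$samples$pct_id_per_g))
})

test_that("study presets reproduce the headline biodistribution structure", {
  pre <- default_study_presets(cv = 0)
  # kidney slow phase: ~12.8 %ID/g at 2 weeks falling to ~0.2 at 12 weeks
  expect_equal(kinetic_mean(pre$kidney, 336), 12.8, tolerance = 0.01)
  expect_equal(kinetic_mean(pre$kidney, 2016), 0.2, tolerance = 0.01)
  # PIP:kidney concentration ratio within 2-3 over weeks 1-3
  for (t in c(168, 336, 504)) {
    ratio <- kinetic_mean(pre$pip_tumor, t) / kinetic_mean(pre$kidney, t)
    expect_true(ratio >= 2 && ratio <= 3)
  }
  # PSMA-negative tumor uptake is minimal
  expect_lte(max(kinetic_mean(pre$flu_tumor, seq(0.5, 504, 0.5))), 1.4)
  # all presets strictly positive over their schedules
  for (m in pre)
    expect_true(all(kinetic_mean(m, m$schedule_h) > 0))
})

test_that("generator truth equals the analytic biexponential integral", {
  sp <- spectrum_fixture
  lp <- decay_constant(sp, "per_hour")
  m <- kinetic_model("toy", 0, c(20, 5), c(0.05, 0.002), cv = 0)
  expect_equal(kinetic_truth_tiac(m, sp),
               0.20 / (0.05 + lp) + 0.05 / (0.002 + lp), tolerance = 1e-12)
  # with the uptake factor, against a fine numeric quadrature oracle
  m2 <- kinetic_model("toy", 8, c(20, 5), c(0.05, 0.002), cv = 0)
  tg <- seq(0, 4e4, by = 0.05)
  oracle <- sum(kinetic_mean(m2, tg) / 100 * exp(-lp * tg)) * 0.05
  expect_equal(kinetic_truth_tiac(m2, sp), oracle, tolerance = 1e-3)
})

test_that("the pipeline recovers TIAC without material bias", {
  m0 <- kinetic_model("toy", 0, c(20, 5), c(0.05, 0.002), cv = 0)
  r0 <- suppressWarnings(
    recovery_experiment(m0, spectrum_fixture, replicates = 1, seed = 1))
  expect_lt(abs(r0$bias), 0.01)
  m <- kinetic_model("toy", 0, c(20, 5), c(0.05, 0.002), cv = 0.2,
                     n_animals = 5)
  r <- suppressWarnings(
    recovery_experiment(m, spectrum_fixture, replicates = 50, seed = 1))
  expect_lt(abs(r$bias), 0.10)
  expect_error(recovery_experiment(m, spectrum_fixture, replicates = 0),
               "replicates")
})

test_that("model validation and CSV round trip", {
  expect_error(kinetic_model("x", 0, c(-1, 0), c(0.1, 0.1)), "amplitudes")
  expect_error(kinetic_model("x", 0, c(1, 1), c(0, 0.1)), "decay constants")
  expect_error(kinetic_model("x", 0, c(1, 0), c(0.1, NA), schedule_h = c()),
               "schedule")
  gen <- generate_biodistribution(default_study_presets(cv = 0.1),
                                  spectrum_fixture, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_biodistribution(gen, path)
  back <- load_biodistribution(path)
  expect_setequal(names(back), gen$truth$tissue)
  expect_equal(back$kidney$samples$pct_id_per_g,
               gen$series$kidney$samples$pct_id_per_g, tolerance = 1e-9)
  expect_true(file.exists(paste0(path, ".truth.json")))
})
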