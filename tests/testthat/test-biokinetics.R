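test_that("biodistribution CSV loads one validated series per tissue", {
  path <- write_toy_csv()
  series <- load_biodistribution(path)
  expect_length(series, 3)
  expect_equal(vapply(series, function(s) nrow(s$samples), integer(1)),
               c(a = 3L, b = 4L, c = 2L))
})

test_that("saturated rows become explicit gaps, never zeros", {
  path <- tempfile(fileext = ".csv")
  df <- data.frame(tissue = "kidney", time_h = c(1, 24, 48, 96, 336),
                   pct_id_per_g = c(NA, NA, 40, 31.4, 9.49),
                   sd = 0, n = 5,
                   flag = c("saturated", "saturated", "ok", "ok", "ok"))
  write.csv(df, path, row.names = FALSE)
  s <- load_biodistribution(path)$kidney
  expect_true(all(is.na(s$samples$pct_id_per_g[s$samples$flag == "saturated"])))
  # saturated rows are excluded from fitting, not treated as zeros
  tac <- fit_tail_exponential(apply_physical_decay(s, spectrum_fixture,
                                                   "to_physical"))
  expect_equal(tac$n_tail, 3)
})

test_that("malformed tables are rejected", {
  path <- tempfile(fileext = ".csv")
  df <- data.frame(tissue = "a", time_h = c(1, 1, 24), pct_id_per_g = 1:3,
                   sd = 0, n = 5)
  write.csv(df, path, row.names = FALSE)
  expect_error(load_biodistribution(path), "duplicate")
  df2 <- data.frame(tissue = "a", time_h = c(1, 24), pct_id_per_g = c(2, -1),
                    sd = 0, n = 5)
  write.csv(df2, path, row.names = FALSE)
  expect_error(load_biodistribution(path), "negative")
  df3 <- data.frame(tissue = "a", time_h = 1, value = 2)
  write.csv(df3, path, row.names = FALSE)
  expect_error(load_biodistribution(path), "missing columns")
})

test_that("physical decay is applied at the radionuclide half-life and inverts exactly", {
  s <- biodist_series("toy", c(0, 59 * 24), c(8, 8), decay_corrected = TRUE)
  phys <- apply_physical_decay(s, spectrum_fixture, "to_physical")
  expect_equal(phys$samples$pct_id_per_g[1], 8)          # t = 0 unchanged
  expect_equal(phys$samples$pct_id_per_g[2], 4)          # one half-life
  back <- apply_physical_decay(phys, spectrum_fixture, "to_corrected")
  expect_equal(back$samples$pct_id_per_g, s$samples$pct_id_per_g,
               tolerance = 1e-12)
  s_unknown <- s
  s_unknown$decay_corrected <- NA
  expect_error(apply_physical_decay(s_unknown, spectrum_fixture), "unknown")
})

test_that("pure mono-exponential data break at the first point with R2 = 1", {
  s <- monoexp_series(c0 = 10, lambda = 0.01)
  tac <- fit_tail_exponential(s)
  expect_equal(tac$tail_start_h, 0)
  expect_equal(tac$fit_r2, 1, tolerance = 1e-9)
  expect_equal(tac$lambda_eff, 0.01, tolerance = 1e-9)
  expect_equal(tac$tail_amplitude, 0.10, tolerance = 1e-9)
})

test_that("breakpoint matches an exhaustive scan oracle on rise-then-fall data", {
  times <- 1:6 * 24
  vals <- c(5, 10 * exp(-0.02 * (times[-1] - 48)))  # peak at the 2nd point
  s <- biodist_series("toy", times, vals, decay_corrected = FALSE)
  tac <- fit_tail_exponential(s, 0.9)
  # oracle: earliest suffix of >= 3 points whose log-linear fit has R2 >= 0.9
  oracle_bp <- NA
  for (b in 1:(length(times) - 2)) {
    fit <- lm(log(vals[b:6] / 100) ~ times[b:6])
    yb <- log(vals[b:6] / 100)
    r2 <- 1 - sum(residuals(fit)^2) / sum((yb - mean(yb))^2)
    if (r2 >= 0.9) {
      oracle_bp <- b
      break
    }
  }
  expect_equal(tac$tail_start_h, times[oracle_bp])
  expect_equal(tac$tail_start_h, 48)  # the peak
})

test_that("kidney-style two-phase tail recovers the closed-form effective half-life", {
  # three points lying exactly on the exponential through 12.8 %ID/g at
  # 2 weeks and 0.2 %ID/g at 12 weeks: t1/2_eff = 10 ln2 / ln64 weeks
  lam <- log(64) / (10 * 7 * 24)
  times <- c(336, 1176, 2016)
  s <- biodist_series("kidney", times, 12.8 * exp(-lam * (times - 336)),
                      decay_corrected = FALSE)
  tac <- fit_tail_exponential(s)
  t_half_wk <- log(2) / tac$lambda_eff / (7 * 24)
  expect_equal(t_half_wk, 10 * log(2) / log(64), tolerance = 1e-6)
  expect_equal(t_half_wk, 1.667, tolerance = 1e-3)
})

test_that("unfittable tails raise an actionable error", {
  s <- biodist_series("zig", c(1, 24, 48, 72, 96), c(10, 1, 10, 1, 10),
                      decay_corrected = FALSE)
  expect_error(fit_tail_exponential(s, 0.9), "relax the threshold")
  expect_error(fit_tail_exponential(monoexp_series(), r2_threshold = 1.2),
               "r2_threshold")
  s2 <- biodist_series("short", c(1, 24), c(5, 4), decay_corrected = FALSE)
  expect_error(fit_tail_exponential(s2), "at least 3")
})

test_that("TIAC closed forms: constant retention and single exponential", {
  lam_p <- decay_constant(spectrum_fixture, "per_hour")
  # constant biological retention, physical decay only -> c0 / lambda_phys
  times <- c(0, 500, 1000, 2000, 4000)
  s <- biodist_series("const", times, rep(7, 5), decay_corrected = TRUE)
  ti <- tiac_from_series(s, spectrum_fixture)
  expect_equal(ti$value_mbq_h_per_g, 0.07 / lam_p, tolerance = 1e-6)
  # single exponential amplitude c0, lambda_eff -> c0 / lambda_eff
  s2 <- monoexp_series(c0 = 10, lambda = 0.01,
                       times = c(0, 100, 200, 400, 800))
  ti2 <- time_integrated_activity(fit_tail_exponential(s2))
  expect_equal(ti2$value_mbq_h_per_g, 0.10 / 0.01, tolerance = 1e-9)
  expect_gt(ti2$value_mbq_h_per_g, 0)
})

test_that("head + tail integral matches a fine-grid quadrature oracle", {
  # 3-node trapezoid head followed by an analytic exponential tail
  times <- c(10, 30, 60, 120, 240, 480)
  vals <- c(2, 9, 4, 4 * exp(-0.008 * (c(120, 240, 480) - 60)))
  s <- biodist_series("toy", times, vals, decay_corrected = FALSE)
  # tight threshold pins the breakpoint to the exactly-exponential suffix
  tac <- fit_tail_exponential(s, r2_threshold = 0.999)
  expect_equal(tac$tail_start_h, 60)
  ti <- time_integrated_activity(tac, head_extrapolation = "flat")
  # oracle: 1e6-step Riemann sum over the same piecewise curve
  tg <- seq(0, 60, length.out = 1e6)
  cg <- approx(c(0, times[1:3]), c(vals[1], vals[1:3]) / 100, xout = tg)$y
  head_o <- sum(cg) * (tg[2] - tg[1])
  tail_o <- tac$tail_amplitude * exp(-tac$lambda_eff * 60) / tac$lambda_eff
  expect_equal(ti$value_mbq_h_per_g, head_o + tail_o, tolerance = 1e-3)
  expect_true(ti$extrapolated_fraction >= 0 && ti$extrapolated_fraction <= 1)
})

test_that("TIAC is monotone in tail half-life and survives the decay round trip", {
  # monotonicity: same data, manually slowed tail
  tac <- fit_tail_exponential(monoexp_series(c0 = 10, lambda = 0.01))
  tac_slow <- tac
  tac_slow$lambda_eff <- 0.005
  expect_gt(time_integrated_activity(tac_slow)$value_mbq_h_per_g,
            time_integrated_activity(tac)$value_mbq_h_per_g)
  # round trip: corrected-then-restored data give the same TIAC as physical
  phys <- monoexp_series(c0 = 10, lambda = 0.005,
                         times = c(0, 100, 300, 700, 1500))
  corr <- apply_physical_decay(phys, spectrum_fixture, "to_corrected")
  ti_phys <- tiac_from_series(phys, spectrum_fixture)
  ti_rt <- tiac_from_series(corr, spectrum_fixture)
  expect_equal(ti_rt$value_mbq_h_per_g, ti_phys$value_mbq_h_per_g,
               tolerance = 1e-9)
  # non-integrable tail rejected
  rising <- biodist_series("up", c(0, 100, 200, 400), c(1, 2, 4, 16),
                           decay_corrected = FALSE)
  expect_error(time_integrated_activity(fit_tail_exponential(rising)),
               "non-integrable")
})
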