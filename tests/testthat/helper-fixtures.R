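# Shared fixtures: tiny biodistribution tables and series built in code.

spectrum_fixture <- default_i125_spectrum()

# A physical (decay-included) series lying exactly on one exponential.
monoexp_series <- function(tissue = "toy", c0 = 10, lambda = 0.01,
                           times = c(0, 24, 48, 96, 192)) {
  biodist_series(tissue, times, c0 * exp(-lambda * times),
                 decay_corrected = FALSE)
}

# Three-tissue toy CSV on disk; returns the path.
write_toy_csv <- function(path = tempfile(fileext = ".csv")) {
  df <- rbind(
    data.frame(tissue = "a", time_h = c(1, 24, 48), pct_id_per_g = c(5, 3, 2),
               sd = 0.1, n = 5, flag = "ok"),
    data.frame(tissue = "b", time_h = c(1, 24, 48, 96),
               pct_id_per_g = c(9, 6, 4, 2), sd = 0.2, n = 4, flag = "ok"),
    data.frame(tissue = "c", time_h = c(24, 48), pct_id_per_g = c(1, 0.5),
               sd = 0.05, n = 5, flag = "ok")
  )
  write.csv(df, path, row.names = FALSE)
  path
}
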