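# Time-activity curve construction from %ID/g biodistribution tables and
# integration to time-integrated activity coefficients (TIAC).
#
# Conventions: concentrations are handled internally as fraction of injected
# activity per gram (%ID/g divided by 100); TIAC is expressed in MBq.h/g per
# MBq injected, i.e. hours x fraction/g, which converts to decays/g per MBq
# by multiplying with 3.6e9.

.TIAC_H_TO_DECAYS <- 3.6e9  # (1e6 decays/s per MBq) * 3600 s/h

#' Construct a biodistribution series
#'
#' @param tissue Tissue label.
#' @param time_h Sampling times post-injection, hours (strictly increasing).
#' @param pct_id_per_g Mean concentration, %ID/g. May be `NA` for rows
#'   flagged `"saturated"` or `"below_lod"` (explicit gaps, never zeros).
#' @param sd Standard deviation of the concentration, %ID/g.
#' @param n Animals per time point (>= 1).
#' @param flag Per-row flag, one of `"ok"`, `"saturated"`, `"below_lod"`.
#' @param decay_corrected Logical: are concentrations decay-corrected to the
#'   time of injection (biological retention), or physical activity?
#' @return An object of class `biodist_series`.
#' @export
biodist_series <- function(tissue, time_h, pct_id_per_g,
                           sd = rep(0, length(time_h)),
                           n = rep(1L, length(time_h)),
                           flag = rep("ok", length(time_h)),
                           decay_corrected = TRUE) {
  if (is.unsorted(time_h, strictly = TRUE))
    stop("times must be strictly increasing (duplicates not allowed): ", tissue)
  if (any(time_h < 0)) stop("negative times in series: ", tissue)
  bad <- !flag %in% c("ok", "saturated", "below_lod")
  if (any(bad)) stop("unknown flag value(s): ", paste(unique(flag[bad]), collapse = ", "))
  quant <- flag == "ok"
  if (any(quant & (is.na(pct_id_per_g) | pct_id_per_g < 0)))
    stop("missing or negative concentrations on rows flagged 'ok': ", tissue)
  if (any(n < 1)) stop("n must be >= 1: ", tissue)
  structure(list(
    tissue = tissue,
    samples = data.frame(time_h = time_h, pct_id_per_g = pct_id_per_g,
                         sd = sd, n = as.integer(n), flag = flag),
    decay_corrected = isTRUE(decay_corrected)
  ), class = "biodist_series")
}

#' @export
print.biodist_series <- function(x, ...) {
  cat(sprintf("<biodist_series> %s: %d time points (%s), %s\n", x$tissue,
              nrow(x$samples),
              paste(range(x$samples$time_h), collapse = "-"),
              if (x$decay_corrected) "decay-corrected" else "physical"))
  invisible(x)
}

#' Load biodistribution series from a CSV table
#'
#' Expected columns: `tissue`, `time_h`, `pct_id_per_g`, `sd`, `n` and an
#' optional `flag` column (`ok`/`saturated`/`below_lod`).  Saturated or
#' below-LOD rows are kept as explicit gaps (`NA` concentration allowed) and
#' excluded from curve fitting downstream.
#'
#' @param path CSV file path.
#' @param decay_corrected Convention of the stored concentrations.
#' @return A named list of `biodist_series`, one per tissue.
#' @export
load_biodistribution <- function(path, decay_corrected = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tissue", "time_h", "pct_id_per_g", "sd", "n")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("biodistribution table missing columns: ", paste(miss, collapse = ", "))
  if (is.null(df$flag)) df$flag <- "ok"
  out <- lapply(split(df, df$tissue), function(d) {
    d <- d[order(d$time_h), , drop = FALSE]
    if (anyDuplicated(d$time_h))
      stop("duplicate time rows for tissue: ", d$tissue[1])
    biodist_series(d$tissue[1], d$time_h, d$pct_id_per_g, d$sd, d$n, d$flag,
                   decay_corrected = decay_corrected)
  })
  out[unique(df$tissue)]
}

#' Apply or remove physical decay on a biodistribution series
#'
#' Dose computation requires physical activity (decays that actually occur);
#' gamma-counting with a same-time injection standard yields decay-corrected
#' biological retention.  `mode = "to_physical"` re-applies the exponential
#' physical decay of the radionuclide; `mode = "to_corrected"` inverts it.
#' The transformation is exactly invertible and is a no-op when the series
#' is already in the requested convention.
#'
#' @param series A `biodist_series`.
#' @param spectrum An `emission_spectrum` (supplies the half-life).
#' @param mode `"to_physical"` or `"to_corrected"`.
#' @return The transformed `biodist_series`.
#' @export
apply_physical_decay <- function(series, spectrum,
                                 mode = c("to_physical", "to_corrected")) {
  mode <- match.arg(mode)
  if (is.null(series$decay_corrected) || is.na(series$decay_corrected))
    stop("decay_corrected flag of series is unknown")
  lam <- decay_constant(spectrum, "per_hour")
  s <- series
  if (mode == "to_physical" && series$decay_corrected) {
    s$samples$pct_id_per_g <- s$samples$pct_id_per_g * exp(-lam * s$samples$time_h)
    s$samples$sd <- s$samples$sd * exp(-lam * s$samples$time_h)
    s$decay_corrected <- FALSE
  } else if (mode == "to_corrected" && !series$decay_corrected) {
    s$samples$pct_id_per_g <- s$samples$pct_id_per_g * exp(lam * s$samples$time_h)
    s$samples$sd <- s$samples$sd * exp(lam * s$samples$time_h)
    s$decay_corrected <- TRUE
  }
  s
}

#' Fit a hybrid trapezoid / mono-exponential time-activity curve
#'
#' Scans breakpoints from the earliest time point: the tail is the earliest
#' suffix of at least three quantified points whose log-linear least-squares
#' fit reaches the requested R-squared; all points before the breakpoint
#' form the trapezoid head.  The fit is performed on the physical
#' (decay-included) series, so the fitted decay constant is the effective
#' (biological + physical) clearance rate.
#'
#' @param series A `biodist_series` in physical convention (a
#'   decay-corrected series is converted internally when `spectrum` is
#'   supplied; otherwise an error is raised).
#' @param r2_threshold Minimum tail R-squared (default 0.9).
#' @param spectrum Optional `emission_spectrum` used to re-apply physical
#'   decay when the input series is decay-corrected.
#' @return An object of class `tac`: head nodes, tail amplitude (fraction/g
#'   at t = 0), effective decay constant (1/h), tail start time, and fit
#'   R-squared.
#' @export
fit_tail_exponential <- function(series, r2_threshold = 0.9, spectrum = NULL) {
  if (!(r2_threshold > 0 && r2_threshold < 1))
    stop("r2_threshold must lie in (0, 1)")
  if (series$decay_corrected) {
    if (is.null(spectrum))
      stop("series is decay-corrected; supply `spectrum` so physical decay can be re-applied")
    series <- apply_physical_decay(series, spectrum, "to_physical")
  }
  d <- series$samples[series$samples$flag == "ok", , drop = FALSE]
  zero <- d$pct_id_per_g <= 0
  if (any(zero)) {
    warning(sprintf("%s: %d non-positive tail value(s) excluded from log fit",
                    series$tissue, sum(zero)))
    d <- d[!zero, , drop = FALSE]
  }
  if (nrow(d) < 3) stop("need at least 3 quantified time points: ", series$tissue)
  t <- d$time_h
  y <- log(d$pct_id_per_g / 100)
  n <- length(t)
  for (b in seq_len(n - 2)) {
    idx <- b:n
    fit <- stats::lm.fit(cbind(1, t[idx]), y[idx])
    res <- fit$residuals
    sst <- sum((y[idx] - mean(y[idx]))^2)
    r2 <- if (sst < 1e-12) as.numeric(sum(res^2) < 1e-12) else 1 - sum(res^2) / sst
    if (r2 >= r2_threshold) {
      lam <- -fit$coefficients[2]
      tac <- structure(list(
        tissue = series$tissue,
        head = data.frame(time_h = d$time_h[seq_len(b)],
                          conc = d$pct_id_per_g[seq_len(b)] / 100),
        tail_amplitude = unname(exp(fit$coefficients[1])),  # fraction/g at t = 0
        lambda_eff = unname(lam),
        tail_start_h = t[b],
        t_last_h = t[n],
        fit_r2 = r2,
        n_tail = length(idx)
      ), class = "tac")
      if (lam > 0) {
        cont <- abs(tac$tail_amplitude * exp(-lam * t[b]) - d$pct_id_per_g[b] / 100) /
          (d$pct_id_per_g[b] / 100)
        if (cont > 0.10)
          warning(sprintf("%s: head/tail mismatch at breakpoint: %.1f%%",
                          series$tissue, 100 * cont))
      }
      return(tac)
    }
  }
  stop(sprintf(paste0("%s: no breakpoint gives a mono-exponential tail with ",
                      "R^2 >= %.2f; relax the threshold or supply more/later ",
                      "time points"), series$tissue, r2_threshold))
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %s: breakpoint %.3g h, lambda_eff %.3g /h (t1/2 %.3g h), R2 %.4f\n",
              x$tissue, x$tail_start_h, x$lambda_eff,
              log(2) / x$lambda_eff, x$fit_r2))
  invisible(x)
}

#' Time-integrated activity coefficient from a fitted curve
#'
#' Trapezoid integral over the head (with a configurable extrapolation from
#' t = 0 to the first quantified point) plus the analytic tail integral
#' `A exp(-lambda t_b) / lambda` extrapolated to infinity.
#'
#' @param curve A `tac` object.
#' @param head_extrapolation Treatment of the unobserved interval before the
#'   first quantified point: `"flat"` (constant back-extrapolation of the
#'   first value, conservative default), `"zero"` (linear ramp from zero at
#'   injection), or `"none"`.
#' @return An object of class `tiac`: `value_mbq_h_per_g` (MBq.h/g per MBq
#'   injected), `value_decays_per_g` (per MBq), the breakpoint time, and
#'   `extrapolated_fraction` (share of the integral beyond the last datum).
#' @export
time_integrated_activity <- function(curve,
                                     head_extrapolation = c("flat", "zero", "none")) {
  head_extrapolation <- match.arg(head_extrapolation)
  if (curve$lambda_eff <= 0)
    stop("non-integrable tail: effective decay constant must be > 0 (",
         curve$tissue, ")")
  h <- curve$head
  head_int <- 0
  if (h$time_h[1] > 0) {
    head_int <- head_int + switch(head_extrapolation,
      flat = h$conc[1] * h$time_h[1],
      zero = 0.5 * h$conc[1] * h$time_h[1],
      none = 0)
  }
  if (nrow(h) > 1) {
    dt <- diff(h$time_h)
    head_int <- head_int + sum(0.5 * (h$conc[-1] + h$conc[-nrow(h)]) * dt)
  }
  c_b <- curve$tail_amplitude * exp(-curve$lambda_eff * curve$tail_start_h)
  tail_int <- c_b / curve$lambda_eff
  total <- head_int + tail_int
  beyond <- curve$tail_amplitude *
    exp(-curve$lambda_eff * curve$t_last_h) / curve$lambda_eff
  structure(list(
    tissue = curve$tissue,
    value_mbq_h_per_g = unname(total),
    value_decays_per_g = unname(total * .TIAC_H_TO_DECAYS),
    breakpoint_time_h = curve$tail_start_h,
    head_integral = unname(head_int),
    tail_integral = unname(tail_int),
    extrapolated_fraction = unname(beyond / total),
    head_extrapolation = head_extrapolation
  ), class = "tiac")
}

#' @export
print.tiac <- function(x, ...) {
  cat(sprintf("<tiac> %s: %.4g MBq.h/g per MBq (breakpoint %.3g h, head %.3g + tail %.3g)\n",
              x$tissue, x$value_mbq_h_per_g, x$breakpoint_time_h,
              x$head_integral, x$tail_integral))
  invisible(x)
}

#' Fit and integrate in one step
#'
#' Convenience wrapper: physical-decay handling, tail fit, and integration
#' for one series, returning the `tiac` with the `tac` attached.
#'
#' @inheritParams fit_tail_exponential
#' @inheritParams time_integrated_activity
#' @return A `tiac` with attribute `tac`.
#' @export
tiac_from_series <- function(series, spectrum, r2_threshold = 0.9,
                             head_extrapolation = "flat") {
  curve <- fit_tail_exponential(series, r2_threshold, spectrum = spectrum)
  ti <- time_integrated_activity(curve, head_extrapolation)
  attr(ti, "tac") <- curve
  ti
}
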