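# Organ absorbed-dose coefficients and doses from TIACs, following the MIRD
# schema: dose = time-integrated activity x energy per decay x absorbed
# fraction / target mass.  Electron and photon channels are kept separate
# throughout (different ranges imply different absorbed fractions and,
# potentially, different biological effectiveness).

#' Organ model
#'
#' @param name Organ label.
#' @param mass_g Organ mass in grams (default 0.298 g: MIRD Pamphlet 19
#'   kidney outline scaled to the mouse).
#' @param photon_af Photon self-absorbed fraction in (0, 1); may be `NA`
#'   until estimated (e.g. by [kidney_photon_af()]).
#' @return An object of class `organ_model`.
#' @export
organ_model <- function(name, mass_g = 0.298, photon_af = NA_real_) {
  if (mass_g <= 0) stop("organ mass must be > 0")
  if (!is.na(photon_af) && !(photon_af > 0 && photon_af < 1))
    stop("photon absorbed fraction must lie in (0, 1)")
  structure(list(name = name, mass_g = mass_g, photon_af = photon_af),
            class = "organ_model")
}

# TIAC input normalization: accepts a `tiac` object or a bare number in
# MBq.h/g per MBq.
.tiac_value_h <- function(tiac) {
  if (inherits(tiac, "tiac")) tiac$value_mbq_h_per_g
  else if (is.numeric(tiac) && length(tiac) == 1) tiac
  else stop("tiac must be a `tiac` object or a single numeric (MBq.h/g per MBq)")
}

#' Electron-channel absorbed dose coefficient
#'
#' Auger/conversion electron ranges (< 10 um) are negligible at organ scale,
#' so the organ-level electron absorbed fraction is 1 and the coefficient is
#' simply TIAC (decays/g per MBq) x electron energy per decay (J) x 1000 g/kg.
#'
#' @param tiac A `tiac` object or numeric TIAC in MBq.h/g per MBq.
#' @param spectrum An `emission_spectrum`.
#' @return Absorbed dose coefficient, Gy/MBq.
#' @export
electron_dose_coefficient <- function(tiac, spectrum) {
  v_h <- .tiac_value_h(tiac)
  if (v_h < 0) stop("TIAC must be >= 0")
  decays_per_g <- v_h * .TIAC_H_TO_DECAYS
  e_j <- spectrum$electron_kev_per_decay * .KEV_TO_J
  decays_per_g * e_j * 1000
}

#' Photon-channel absorbed dose coefficient (self-dose)
#'
#' Scales the electron-channel formula by the photon/electron per-decay
#' energy ratio and the organ's photon self-absorbed fraction.  Cross-organ
#' photon dose is out of scope (self-dose only).
#'
#' @inheritParams electron_dose_coefficient
#' @param organ An `organ_model` with `photon_af` set, or a bare absorbed
#'   fraction in (0, 1).
#' @return Absorbed dose coefficient, Gy/MBq.
#' @export
photon_dose_coefficient <- function(tiac, spectrum, organ) {
  af <- if (inherits(organ, "organ_model")) organ$photon_af else organ
  if (is.null(af) || is.na(af))
    stop("photon absorbed fraction missing; estimate it first (e.g. kidney_photon_af)")
  if (af < 0 || af >= 1) stop("photon absorbed fraction must lie in [0, 1)")
  ratio <- spectrum$photon_kev_per_decay / spectrum$electron_kev_per_decay
  electron_dose_coefficient(tiac, spectrum) * ratio * af
}

#' Absorbed dose at a given injected activity
#'
#' @param coeff_gy_per_mbq Dose coefficient, Gy/MBq (vectorized).
#' @param injected_mbq Injected activity, MBq (>= 0).
#' @return Absorbed dose, Gy.
#' @export
dose_at_activity <- function(coeff_gy_per_mbq, injected_mbq) {
  if (any(injected_mbq < 0)) stop("injected activity must be >= 0")
  coeff_gy_per_mbq * injected_mbq
}

#' Build a per-organ dose report
#'
#' @param coefficients A data frame (or list coercible to one) with columns
#'   `organ`, `electron_gy_per_mbq`, `photon_gy_per_mbq` (photon may be NA
#'   when no absorbed fraction is available for that organ).
#' @param injected_mbq Injected activity, MBq.
#' @param provenance Optional named list recorded verbatim in the report.
#' @return An object of class `dose_report`: the coefficient table with
#'   electron/photon/total doses at `injected_mbq`, plus provenance.
#' @export
build_dose_report <- function(coefficients, injected_mbq, provenance = list()) {
  df <- as.data.frame(coefficients)
  need <- c("organ", "electron_gy_per_mbq", "photon_gy_per_mbq")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) < 1) stop("need at least one coefficient row")
  if (anyDuplicated(df$organ)) stop("duplicate organ entries")
  if (any(injected_mbq < 0)) stop("injected activity must be >= 0")
  df$electron_gy <- df$electron_gy_per_mbq * injected_mbq
  df$photon_gy <- df$photon_gy_per_mbq * injected_mbq
  df$total_gy <- df$electron_gy + ifelse(is.na(df$photon_gy), 0, df$photon_gy)
  structure(list(injected_mbq = injected_mbq, organs = df,
                 provenance = provenance),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat(sprintf("<dose_report> injected activity %.4g MBq\n", x$injected_mbq))
  print(x$organs[c("organ", "electron_gy_per_mbq", "photon_gy_per_mbq",
                   "electron_gy", "photon_gy", "total_gy")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Serialize / deserialize a dose report as JSON
#'
#' @param report A `dose_report`.
#' @param path File path.
#' @return `read_dose_report` returns the `dose_report`.
#' @export
write_dose_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_dose_report
#' @export
read_dose_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(injected_mbq = obj$injected_mbq,
                 organs = as.data.frame(obj$organs),
                 provenance = obj$provenance),
            class = "dose_report")
}
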