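# Nephron-scale dosimetry: energy partition of I-125 electron emissions in a
# proximal-tubule micro-model, and the proximal-tubule nuclear dose implied
# by a whole-kidney electron dose.
#
# Geometry: an infinite annular cylinder - lumen of configurable radius
# surrounded by a 10 um epithelial wall.  Tubule-cell nuclei are 5 um
# spheres centred mid-wall, one per epithelial cell of lateral pitch
# `cell_pitch_um`.  Two nucleus treatments: a packing-fraction average over
# the mid-wall nuclear band (fast, low-variance default) and an explicit
# sphere lattice (validation mode).  Electron transport is the same
# straight-track CSDA model as the cellular module.

#' Nephron (proximal tubule) micro-geometry
#'
#' @param wall_um Tubule wall (epithelium) thickness, micrometres (default 10).
#' @param nucleus_um Tubule-cell nucleus diameter, micrometres (default 5).
#' @param lumen_radius_um Lumen radius, micrometres (default 15, a typical
#'   murine proximal tubule; the source nephron model does not reprint it).
#' @param occupancy Fractional occupancy of the kidney by proximal-tubule
#'   cells (default 0.43).
#' @param cell_pitch_um Lateral size of an epithelial cell in the wall
#'   (default 14 um, the large proximal-tubule epithelial cell of the
#'   human-scale nephron model this geometry descends from; one 5 um
#'   nucleus per cell).
#' @param kidney_nuclear_fraction Nuclear mass fraction of the whole kidney
#'   used to normalize nuclear doses (default 0.134, a typical nuclear
#'   volume density of cell-dense renal cortex).  Kept separate from the
#'   in-wall packing: the kidney contains nuclei of all nephron segments,
#'   glomeruli and interstitium, not only the sparse proximal-tubule wall
#'   nuclei.
#' @return Object of class `nephron_geometry`, including the derived
#'   nuclear packing fraction of the mid-wall band
#'   (`band_packing`) and of the whole wall (`wall_nuclear_fraction`).
#' @export
nephron_geometry <- function(wall_um = 10, nucleus_um = 5,
                             lumen_radius_um = 15, occupancy = 0.43,
                             cell_pitch_um = 14,
                             kidney_nuclear_fraction = 0.134) {
  if (any(c(wall_um, nucleus_um, lumen_radius_um, cell_pitch_um) <= 0))
    stop("all lengths must be > 0")
  if (nucleus_um > wall_um)
    stop("nucleus cannot be larger than the wall thickness")
  if (!(occupancy > 0 && occupancy < 1)) stop("occupancy must lie in (0, 1)")
  if (!(kidney_nuclear_fraction > 0 && kidney_nuclear_fraction < 1))
    stop("kidney_nuclear_fraction must lie in (0, 1)")
  v_nuc <- 4 / 3 * pi * (nucleus_um / 2)^3
  structure(list(
    wall_um = wall_um, nucleus_um = nucleus_um,
    lumen_radius_um = lumen_radius_um, occupancy = occupancy,
    cell_pitch_um = cell_pitch_um,
    kidney_nuclear_fraction = kidney_nuclear_fraction,
    r_lumen = lumen_radius_um,
    r_outer = lumen_radius_um + wall_um,
    r_mid = lumen_radius_um + wall_um / 2,
    band_in = lumen_radius_um + wall_um / 2 - nucleus_um / 2,
    band_out = lumen_radius_um + wall_um / 2 + nucleus_um / 2,
    band_packing = v_nuc / (cell_pitch_um^2 * nucleus_um),
    wall_nuclear_fraction = v_nuc / (cell_pitch_um^2 * wall_um)
  ), class = "nephron_geometry")
}

#' Energy partition of tubule decays
#'
#' Seeded straight-track CSDA transport of the grouped \eqn{^{125}}I
#' electron spectrum in the annular tubule, for decays on the apical
#' (luminal) tubule surface or distributed in the wall cytoplasm.  Tracks
#' are partitioned into lumen, wall and beyond-wall deposition; the nuclear
#' share of the wall deposit is obtained either from the mid-wall band
#' weighted by the nuclear packing fraction (`nucleus_mode = "packing"`) or
#' from an explicit lattice of 5 um nuclear spheres
#' (`nucleus_mode = "explicit"`).
#'
#' @param geom A [nephron_geometry()].
#' @param source `"surface"` (apical/luminal surface, the PSMA-bound,
#'   non-internalized case) or `"cytoplasm"` (internalized case).
#' @param spectrum An `emission_spectrum`.
#' @param histories Number of histories.
#' @param seed RNG seed.
#' @param nucleus_mode `"packing"` or `"explicit"`.
#' @param n_steps Track discretization steps per history (boundary blur
#'   < 0.1 um at the default).
#' @return Object of class `tubule_fractions`: energy fractions to
#'   `nucleus`, `cytoplasm`, `lumen`, `beyond_wall` (summing to 1), their
#'   standard errors, and the run parameters.
#' @export
tubule_source_fractions <- function(geom = nephron_geometry(),
                                    source = c("surface", "cytoplasm"),
                                    spectrum = default_i125_spectrum(),
                                    histories = 2e5, seed = 1,
                                    nucleus_mode = c("packing", "explicit"),
                                    n_steps = 128) {
  source <- match.arg(source)
  nucleus_mode <- match.arg(nucleus_mode)
  lines <- spectrum$electron_lines
  w_line <- lines$energy_kev * lines$yield
  w_line <- w_line / sum(w_line)
  res <- with_seed(seed, {
    n <- as.integer(histories)
    li <- sample.int(nrow(lines), n, replace = TRUE, prob = w_line)
    E0 <- lines$energy_kev[li]
    R0 <- electron_range(E0)
    # source position: azimuth/z randomized against the nucleus lattice
    theta <- stats::runif(n, 0, 2 * pi)
    z0 <- stats::runif(n, 0, geom$cell_pitch_um)
    rs <- if (source == "surface") rep(geom$r_lumen, n)
          else sqrt(geom$r_lumen^2 +
                    stats::runif(n) * (geom$r_outer^2 - geom$r_lumen^2))
    px <- rs * cos(theta); py <- rs * sin(theta)
    d <- .random_unit_vectors(n)
    dep <- matrix(0, n, 4,
                  dimnames = list(NULL, c("nucleus", "cytoplasm", "lumen",
                                          "beyond_wall")))
    dth <- geom$cell_pitch_um / geom$r_mid   # angular pitch of the lattice
    e_prev <- E0
    for (j in seq_len(n_steps)) {
      s0 <- (j - 1) / n_steps * R0
      s1 <- j / n_steps * R0
      e_next <- electron_energy_from_range(R0 - s1)
      de <- e_prev - e_next
      e_prev <- e_next
      sm <- (s0 + s1) / 2
      x <- px + d[, 1] * sm; y <- py + d[, 2] * sm; z <- z0 + d[, 3] * sm
      rr <- sqrt(x^2 + y^2)
      region <- ifelse(rr < geom$r_lumen, 3L,            # lumen
                ifelse(rr > geom$r_outer, 4L,            # beyond wall
                ifelse(rr >= geom$band_in & rr <= geom$band_out, 0L, 2L)))
      if (nucleus_mode == "packing") {
        # band deposit split between nuclei and cytoplasm by packing
        in_nuc <- region == 0L
        dep[, 1] <- dep[, 1] + de * in_nuc * geom$band_packing
        dep[, 2] <- dep[, 2] + de * (in_nuc * (1 - geom$band_packing) +
                                     (region == 2L))
      } else {
        # explicit lattice: nearest nucleus centre at r_mid
        th <- atan2(y, x) %% (2 * pi)
        thc <- (floor(th / dth) + 0.5) * dth
        zc <- (floor(z / geom$cell_pitch_um) + 0.5) * geom$cell_pitch_um
        dx <- x - geom$r_mid * cos(thc)
        dy <- y - geom$r_mid * sin(thc)
        dz <- z - zc
        in_sphere <- (dx^2 + dy^2 + dz^2) < (geom$nucleus_um / 2)^2 &
          region %in% c(0L, 2L)
        dep[, 1] <- dep[, 1] + de * in_sphere
        dep[, 2] <- dep[, 2] + de * (!in_sphere & region %in% c(0L, 2L))
      }
      dep[, 3] <- dep[, 3] + de * (region == 3L)
      dep[, 4] <- dep[, 4] + de * (region == 4L)
    }
    fr <- dep / E0
    list(fractions = colMeans(fr),
         se = apply(fr, 2, stats::sd) / sqrt(n))
  })
  structure(c(res, list(source = source, nucleus_mode = nucleus_mode,
                        histories = histories, geom = geom)),
            class = "tubule_fractions")
}

#' @export
print.tubule_fractions <- function(x, ...) {
  cat(sprintf("<tubule_fractions> %s source (%s nuclei, %d histories)\n",
              x$source, x$nucleus_mode, x$histories))
  out <- data.frame(region = names(x$fractions),
                    fraction_pct = 100 * x$fractions,
                    se_pct = 100 * x$se)
  print(out, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Average absorbed dose to proximal-tubule cell nuclei
#'
#' Rescales the whole-kidney electron dose to the proximal-tubule nuclei:
#' activity is localized to the proximal tubules (fractional occupancy of
#' the kidney, default 43%), a fraction \eqn{\phi} of the emitted electron
#' energy reaches tubule-cell nuclei (from [tubule_source_fractions()]),
#' and the normalizing mass is the kidney's nuclear compartment implied by
#' the epithelial geometry (nuclear volume fraction of the tubule wall):
#' \deqn{D_{nuc} = D_{kidney} \times occupancy \times \phi / f_{nuc}.}
#' Every factor is recorded in the returned provenance.
#'
#' @param kidney_coeff_gy_per_mbq Whole-kidney electron-channel dose
#'   coefficient, Gy/MBq.
#' @param injected_mbq Injected activity, MBq.
#' @param fractions A `tubule_fractions` (supplies \eqn{\phi}), or a bare
#'   nuclear energy fraction.
#' @param geom A [nephron_geometry()] (supplies occupancy and the nuclear
#'   mass fraction).
#' @return List with `dose_gy` and `provenance` (each factor of the
#'   formula).
#' @export
proximal_tubule_nuclei_dose <- function(kidney_coeff_gy_per_mbq, injected_mbq,
                                        fractions, geom = nephron_geometry()) {
  if (kidney_coeff_gy_per_mbq < 0 || injected_mbq < 0)
    stop("inputs must be >= 0")
  phi <- if (inherits(fractions, "tubule_fractions"))
    unname(fractions$fractions["nucleus"]) else fractions
  if (is.null(phi) || is.na(phi)) stop("nuclear energy fraction missing")
  f_nuc <- geom$kidney_nuclear_fraction
  kidney_dose <- kidney_coeff_gy_per_mbq * injected_mbq
  dose <- kidney_dose * geom$occupancy * phi / f_nuc
  list(dose_gy = dose,
       provenance = list(kidney_dose_gy = kidney_dose,
                         occupancy = geom$occupancy,
                         phi_nucleus = phi,
                         kidney_nuclear_mass_fraction = f_nuc))
}

#' Glomerular absorbed dose
#'
#' The sub-10-um range of the Auger electrons makes their contribution to
#' glomerular cell nuclei negligible; the glomerular dose equals the photon
#' channel dose, regardless of the electron channel magnitude.
#'
#' @param photon_kidney_dose_gy Photon-channel kidney dose, Gy.
#' @return Glomerular dose, Gy (the photon dose passed through).
#' @export
glomerular_dose <- function(photon_kidney_dose_gy) {
  photon_kidney_dose_gy
}

#' Average dose to salivary striated ducts under full duct concentration
#'
#' Worst case in which all salivary activity is concentrated in the
#' PSMA-expressing striated ducts: organ dose divided by the duct mass
#' fraction.
#'
#' @param organ_coeff_gy_per_mbq Organ dose coefficient, Gy/MBq.
#' @param injected_mbq Injected activity, MBq.
#' @param duct_mass_fraction Striated-duct share of organ mass, in (0, 1]
#'   (default 1/20).
#' @return Duct dose, Gy.
#' @export
uniform_duct_dose <- function(organ_coeff_gy_per_mbq, injected_mbq,
                              duct_mass_fraction = 1 / 20) {
  if (!(duct_mass_fraction > 0 && duct_mass_fraction <= 1))
    stop("duct mass fraction must lie in (0, 1]")
  organ_coeff_gy_per_mbq * injected_mbq / duct_mass_fraction
}
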