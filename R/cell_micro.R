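# Cellular-scale dosimetry in a concentric-sphere cell: fraction of emitted
# Auger/conversion-electron energy deposited in the nucleus for perinuclear,
# membrane, cytoplasmic and intranuclear sources.
#
# Electron transport model: straight-track continuous-slowing-down (CSDA)
# with the Cole range-energy relation.  An electron of initial energy E0
# travels a straight line of length R(E0); its residual energy after path s
# is E(R(E0) - s), and the energy deposited in any region is the difference
# of residual energies at the region's entry and exit points.  Energy is
# conserved exactly per history.  Two backends: seeded Monte Carlo over
# isotropic directions, and a deterministic point kernel (Gauss-Legendre
# quadrature over emission angle and source radius).

#' Concentric-sphere cell geometry
#'
#' @param cell_um Cell diameter, micrometres (default 26).
#' @param nucleus_um Nucleus diameter, micrometres (default 18); the nucleus
#'   is concentric with the cell.
#' @return Object of class `cell_geometry`.
#' @export
cell_geometry <- function(cell_um = 26, nucleus_um = 18) {
  if (!(nucleus_um > 0 && nucleus_um < cell_um))
    stop("need 0 < nucleus diameter < cell diameter")
  structure(list(cell_um = cell_um, nucleus_um = nucleus_um,
                 r_cell = cell_um / 2, r_nuc = nucleus_um / 2),
            class = "cell_geometry")
}

#' Subcellular source distribution
#'
#' @param perinuclear,membrane,cytoplasm Non-negative fractions summing to 1
#'   (defaults 0.15 / 0.35 / 0.50, the internalization pattern measured for
#'   PSMA-targeted small molecules in PSMA+ tumor cells).
#' @return Named numeric vector of class `source_distribution`.
#' @export
source_distribution <- function(perinuclear = 0.15, membrane = 0.35,
                                cytoplasm = 0.50) {
  v <- c(perinuclear = perinuclear, membrane = membrane, cytoplasm = cytoplasm)
  if (any(v < 0)) stop("fractions must be >= 0")
  if (abs(sum(v) - 1) > 1e-8) stop("fractions must sum to 1")
  structure(v, class = "source_distribution")
}

#' Nuclear volume fraction of the cell
#'
#' @param geom A `cell_geometry`.
#' @return (d_nucleus / d_cell)^3, the nuclear share of cell volume (and of
#'   cell mass at uniform density).
#' @export
nuclear_volume_fraction <- function(geom) {
  (geom$nucleus_um / geom$cell_um)^3
}

# ---- CSDA straight-track kernel --------------------------------------------

# Fraction of a single electron's energy deposited between path lengths
# s1 and s2 (s1 <= s2), for initial energy E0 with total range R0.
.csda_segment_fraction <- function(E0, R0, s1, s2) {
  s1 <- pmin(pmax(s1, 0), R0)
  s2 <- pmin(pmax(s2, 0), R0)
  (electron_energy_from_range(R0 - s1) - electron_energy_from_range(R0 - s2)) / E0
}

# Entry/exit path lengths of a ray (source radius rs, direction cosine mu
# relative to the outward radial direction) through a concentric sphere of
# radius rho.  Returns list(s_in, s_out); s_in = s_out = 0 when missed.
.ray_sphere <- function(rs, mu, rho) {
  n <- max(length(rs), length(mu))
  rs <- rep_len(rs, n)
  mu <- rep_len(mu, n)
  disc <- rs^2 * mu^2 - rs^2 + rho^2
  hit <- disc > 0
  sq <- sqrt(pmax(disc, 0))
  s1 <- -rs * mu - sq
  s2 <- -rs * mu + sq
  inside <- rs < rho
  # sources outside (or exactly on) the sphere enter iff the far root is
  # ahead of them; s1 ~ 0 up to roundoff for an on-surface source
  enters <- hit & s2 > 0
  s_in <- ifelse(inside, 0, ifelse(enters, pmax(s1, 0), 0))
  s_out <- ifelse(inside, pmax(s2, 0), ifelse(enters, s2, 0))
  list(s_in = s_in, s_out = s_out)
}

# Per-emission deposition fractions (nucleus, cytoplasm, outside) for
# electrons of energy E0 emitted at radius rs with direction cosines mu.
.cell_track_fractions <- function(E0, rs, mu, geom) {
  R0 <- electron_range(E0)
  nuc <- .ray_sphere(rs, mu, geom$r_nuc)
  cell <- .ray_sphere(rs, mu, geom$r_cell)
  f_nuc <- .csda_segment_fraction(E0, R0, nuc$s_in, nuc$s_out)
  f_cell <- .csda_segment_fraction(E0, R0, 0, cell$s_out)
  list(nucleus = f_nuc, cytoplasm = f_cell - f_nuc, outside = 1 - f_cell)
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch).
.gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

.sample_source_radius <- function(compartment, n_or_nodes, geom, shell_eps,
                                  quadrature = FALSE) {
  rn <- geom$r_nuc; rc <- geom$r_cell
  switch(compartment,
    perinuclear = list(r = rep(rn + shell_eps, if (quadrature) 1 else n_or_nodes),
                       w = 1),
    membrane = list(r = rep(rc, if (quadrature) 1 else n_or_nodes), w = 1),
    cytoplasm = if (quadrature) {
      gl <- .gauss_legendre(n_or_nodes)
      r <- (rn + rc) / 2 + gl$nodes * (rc - rn) / 2
      w <- gl$weights * (rc - rn) / 2 * 3 * r^2 / (rc^3 - rn^3)
      list(r = r, w = w)
    } else {
      u <- stats::runif(n_or_nodes)
      list(r = (rn^3 + u * (rc^3 - rn^3))^(1 / 3), w = 1)
    },
    nucleus = if (quadrature) {
      gl <- .gauss_legendre(n_or_nodes)
      r <- rn / 2 + gl$nodes * rn / 2
      w <- gl$weights * rn / 2 * 3 * r^2 / rn^3
      list(r = r, w = w)
    } else {
      list(r = rn * stats::runif(n_or_nodes)^(1 / 3), w = 1)
    },
    stop("unknown compartment: ", compartment)
  )
}

#' Fraction of emitted electron energy deposited in the nucleus
#'
#' Straight-track CSDA transport of the grouped \eqn{^{125}}I electron
#' spectrum from a subcellular source compartment, returning the fraction of
#' all emitted electron energy absorbed in the nucleus.
#'
#' Source placement: `"perinuclear"` is an isotropically emitting thin
#' shell on the nuclear surface (standoff `shell_eps_um`, default 0: even a
#' sub-micrometre standoff is large on the scale of the sub-keV Auger
#' ranges and sharply suppresses their nuclear deposit);
#' `"membrane"` sits on the cell surface; `"cytoplasm"` is uniform in the
#' shell between nucleus and membrane; `"nucleus"` is uniform inside the
#' nucleus.
#'
#' @param geom A `cell_geometry`.
#' @param compartment One of `"perinuclear"`, `"membrane"`, `"cytoplasm"`,
#'   `"nucleus"`.
#' @param spectrum An `emission_spectrum`.
#' @param backend `"mc"` (seeded Monte Carlo) or `"point_kernel"`
#'   (deterministic quadrature).
#' @param histories MC histories (ignored by the point kernel).
#' @param seed RNG seed for the MC backend.
#' @param shell_eps_um Perinuclear shell standoff from the nuclear surface
#'   in micrometres (default 0: source on the surface).
#' @param n_quad Quadrature order per dimension for the point kernel.
#' @return List with `phi` (fraction in [0,1]), `se` (MC standard error; 0
#'   for the point kernel), `compartment`, `backend`.
#' @export
compartment_energy_fraction <- function(geom, compartment,
                                        spectrum = default_i125_spectrum(),
                                        backend = c("mc", "point_kernel"),
                                        histories = 1e5, seed = 1,
                                        shell_eps_um = 0, n_quad = 128) {
  backend <- match.arg(backend)
  compartment <- match.arg(compartment,
                           c("perinuclear", "membrane", "cytoplasm", "nucleus"))
  lines <- spectrum$electron_lines
  w_line <- lines$energy_kev * lines$yield
  w_line <- w_line / sum(w_line)
  if (backend == "mc") {
    res <- with_seed(seed, {
      n <- as.integer(histories)
      li <- sample.int(nrow(lines), n, replace = TRUE, prob = w_line)
      E0 <- lines$energy_kev[li]
      src <- .sample_source_radius(compartment, n, geom, shell_eps_um)
      mu <- stats::runif(n, -1, 1)
      fr <- .cell_track_fractions(E0, src$r, mu, geom)
      list(phi = mean(fr$nucleus), se = stats::sd(fr$nucleus) / sqrt(n))
    })
  } else {
    gl <- .gauss_legendre(n_quad)
    src <- .sample_source_radius(compartment, min(n_quad, 64), geom,
                                 shell_eps_um, quadrature = TRUE)
    phi <- 0
    for (l in seq_len(nrow(lines))) {
      E0 <- lines$energy_kev[l]
      for (k in seq_along(src$r)) {
        f <- .cell_track_fractions(E0, src$r[k], gl$nodes, geom)
        # isotropic emission: average over mu with weight 1/2
        phi <- phi + w_line[l] * src$w[k] * sum(gl$weights * f$nucleus) / 2
      }
    }
    res <- list(phi = phi, se = 0)
  }
  c(res, list(compartment = compartment, backend = backend))
}

#' Nuclear deposition fractions for all source compartments
#'
#' @inheritParams compartment_energy_fraction
#' @param compartments Compartments to evaluate.
#' @return Object of class `deposition_fractions`: a data frame with
#'   columns `compartment`, `phi`, `se`, plus the backend used.
#' @export
cell_deposition_fractions <- function(geom = cell_geometry(),
                                      spectrum = default_i125_spectrum(),
                                      backend = c("mc", "point_kernel"),
                                      histories = 1e5, seed = 1,
                                      shell_eps_um = 0,
                                      compartments = c("perinuclear",
                                                       "membrane",
                                                       "cytoplasm")) {
  backend <- match.arg(backend)
  rows <- lapply(seq_along(compartments), function(i) {
    r <- compartment_energy_fraction(geom, compartments[i], spectrum, backend,
                                     histories, seed + i - 1, shell_eps_um)
    data.frame(compartment = compartments[i], phi = r$phi, se = r$se)
  })
  structure(list(fractions = do.call(rbind, rows), backend = backend,
                 geom = geom), class = "deposition_fractions")
}

#' @export
print.deposition_fractions <- function(x, ...) {
  cat(sprintf("<deposition_fractions> backend %s (cell %g um / nucleus %g um)\n",
              x$backend, x$geom$cell_um, x$geom$nucleus_um))
  print(transform(x$fractions, phi_pct = 100 * phi, se_pct = 100 * se),
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Nuclear-to-average dose ratio of the tumor cell
#'
#' Source-distribution-weighted nuclear energy-deposition fraction divided
#' by the nuclear mass fraction: the average nuclear absorbed dose relative
#' to the tumor-average absorbed dose.
#'
#' @param dist A [source_distribution()] (or named vector with entries
#'   `perinuclear`, `membrane`, `cytoplasm`).
#' @param phi Named vector or `deposition_fractions` giving the nuclear
#'   deposition fraction per compartment.
#' @param w_nuc Nuclear mass fraction of the cell, in (0, 1).
#' @return Dimensionless dose ratio.
#' @export
nuclear_dose_ratio <- function(dist, phi, w_nuc) {
  if (!(w_nuc > 0 && w_nuc < 1)) stop("w_nuc must lie in (0, 1)")
  if (inherits(phi, "deposition_fractions"))
    phi <- stats::setNames(phi$fractions$phi, phi$fractions$compartment)
  comp <- names(dist)
  if (!all(comp %in% names(phi)))
    stop("phi must provide a value for every source compartment")
  sum(unclass(dist) * phi[comp]) / w_nuc
}

#' Tumor-cell nuclear absorbed dose
#'
#' @param tumor_coeff_gy_per_mbq Tumor electron-channel dose coefficient,
#'   Gy/MBq.
#' @param injected_mbq Injected activity, MBq.
#' @param ratio Nuclear-to-average dose ratio from [nuclear_dose_ratio()].
#' @return Nuclear absorbed dose, Gy.
#' @export
tumor_nuclear_dose <- function(tumor_coeff_gy_per_mbq, injected_mbq, ratio) {
  if (tumor_coeff_gy_per_mbq < 0 || injected_mbq < 0 || ratio < 0)
    stop("inputs must be >= 0")
  tumor_coeff_gy_per_mbq * injected_mbq * ratio
}
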