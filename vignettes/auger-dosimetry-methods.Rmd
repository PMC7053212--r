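---
title: "Methods: macro-to-microscale dosimetry for an Auger-electron PSMA radioligand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: macro-to-microscale dosimetry for an Auger-electron PSMA radioligand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(augerdose)
```

## The problem

Auger-electron emitters such as ^125^I deposit most of their electron energy
within a few micrometres of the decay site. At the whole-organ scale this
makes dosimetry trivially simple — essentially every emitted electron is
absorbed in the source organ — but it makes the *biological* meaning of an
organ-average absorbed dose unreliable: whether a decay damages DNA depends
on whether it happens within electron range of a cell nucleus. For a
PSMA-targeted small molecule this subcellular geometry differs sharply
between tissues. Tumor cells internalize the ligand (a substantial fraction
ends up perinuclear), while kidney proximal-tubule cells carry PSMA only on
their apical (luminal) brush-border surface, several micrometres from their
nuclei. `augerdose` implements the full chain needed to quantify that
differential: biodistribution kinetics to time-integrated activity, MIRD
organ dose coefficients split into electron and photon channels, photon
absorbed fractions from Monte Carlo transport, and electron microdosimetry
at the cell and nephron scales.

## Pipeline overview

1. **Biokinetics** — `%ID/g` tables → hybrid trapezoid/mono-exponential
   time-activity curves → time-integrated activity coefficients (TIAC,
   MBq·h/g per MBq injected).
2. **Organ dose** — TIAC × energy per decay × absorbed fraction / mass
   (MIRD schema), electron and photon channels kept separate.
3. **Photon transport** — absorbed fractions in unit-density spheres
   (0.001–100 g) and a kidney-mass ellipsoid; power-law summary
   AF(m) = a·m^b.
4. **Cell microdosimetry** — nuclear energy-deposition fractions for
   perinuclear / membrane / cytoplasmic sources in a 26/18 µm
   concentric-sphere cell; nuclear-to-average dose ratio.
5. **Nephron microdosimetry** — energy partition of tubule-surface and
   cytoplasmic decays among nucleus / cytoplasm / lumen / beyond-wall in an
   annular tubule; proximal-tubule nuclear dose.
6. **Synthetic data** — kinetic models with closed-form TIAC truth, so the
   whole pipeline is testable without any external data.

## Emission data

The packaged ^125^I spectrum groups the Auger/Coster–Kronig cascade and the
conversion electrons of the 35.5 keV transition into eight electron groups,
and carries the Te K/L X-rays plus the 35.5 keV gamma as six photon lines.
Group yields are normalized at construction so the per-decay energies equal
the ICRP 107 aggregates used throughout the analysis: 19.2 keV (electrons)
and 42.8 keV (photons) per decay, with a 59-day half-life. The grouping
preserves the feature that matters for microdosimetry: roughly half the
electron energy is carried by sub-4-keV electrons with sub-micrometre
ranges, the other half by 22–35 keV conversion/Auger-K electrons with
ranges of 11–23 µm.

```{r}
default_i125_spectrum()
```

## Biokinetics conventions

Two conventions are handled explicitly. Gamma-counting with a same-time
injection standard yields *decay-corrected* concentrations (biological
retention); absorbed dose needs *physical* activity. `apply_physical_decay`
converts between them exactly, and `fit_tail_exponential` always fits the
physical series, so the fitted tail constant is the effective
(biological + physical) clearance rate and the integral to infinity is
finite even for fully retained activity.

The tail is chosen by scanning breakpoints from the earliest time point:
the earliest suffix of at least three quantified points whose log-linear
least-squares fit reaches R² ≥ 0.9 (configurable) becomes the analytic
tail; earlier points form the trapezoid head. The earliest admissible
breakpoint maximizes the data supporting the analytic tail. Saturated
points (e.g. early kidney samples too hot for the counter) are explicit
gaps, excluded from fitting. For series whose first quantified point is
late, the unobserved head is filled by a flat back-extrapolation of the
first value by default (`"zero"` ramp and `"none"` are available); the
choice is conservative for tissues with early peaks and is recorded in the
TIAC provenance, as is the fraction of the integral extrapolated beyond
the last datum.

## Organ dose

With electron ranges below 10 µm, the organ-level electron absorbed
fraction is 1, so the electron coefficient is TIAC × 19.2 keV expressed in
Gy/MBq. The photon coefficient scales the same TIAC by the photon/electron
per-decay energy ratio (42.8/19.2) times the organ's photon self-absorbed
fraction; photon dose is applied as self-dose only — cross-organ photon
dose is deliberately out of scope. No relative-biological-effectiveness
weighting is applied; channels are reported separately.

## Photon Monte Carlo

Transport physics is deliberately minimal but real: photoelectric
absorption and incoherent (Klein–Nishina) scattering in water. Coherent
scattering deposits no energy and barely perturbs 27–35 keV paths, so it is
excluded. The photoelectric coefficient is inferred from the embedded NIST
water energy-absorption table as µ_pe = µ_en − µ_incoh·⟨T⟩/E, which keeps
the transport exactly consistent with the tabulated energy absorption at
the energies that matter here (3.8–35.5 keV). Compton electrons and
photoelectrons deposit locally (ranges < 30 µm, negligible against phantom
dimensions); scattered photons are followed until escape, photoelectric
absorption, or a 2 keV cutoff. Bodies are convex, so free paths sampled
against the local attenuation coefficient need no boundary tracking: a
collision point outside the body is an escape. The estimator is analogue
per-history energy deposition with lines sampled proportionally to the
energy they carry, giving the energy-weighted absorbed fraction directly
with a per-history standard error.

The kidney uses an ellipsoid of kidney-like axis proportions (1 : 0.55 :
0.37) scaled to 0.298 g — the multi-region pamphlet geometry is not needed
for a whole-organ absorbed fraction of a few percent, and the deviation is
flagged in the output. The 20-sphere study (0.001–100 g, log-spaced) is
summarized by a log-log least-squares power law; the exponent is the
robust quantity of that fit. The absolute level of the simulated absorbed
fractions is sensitive to cross-section detail (e.g. the fate of the ~4 keV
Te L X-rays, binding corrections to incoherent scattering) at the tens of
percent level; the mass exponent is not.

## Cell microdosimetry

Electron transport at the cell scale uses straight-track
continuous-slowing-down (CSDA) transport with the Cole (1969) range–energy
relation, offset-adjusted to vanish at zero energy:
R(µm) = 0.0431·((E + 0.367)^1.77 − 0.367^1.77), E in keV. An electron of
energy E₀ travels a straight line of length R(E₀); its residual energy
after path s is the inverse relation evaluated at R(E₀) − s, and the energy
deposited in any region is the difference of residual energies at entry and
exit. This is the same family of model used by standard cellular S-value
calculators, and energy is conserved exactly per history. Two backends
implement the same physics — a seeded Monte Carlo over isotropic emission
directions, and a deterministic Gauss–Legendre point kernel (128 angular
nodes, up to 64 radial nodes for volume sources) — and agreement between
them is enforced by tests.

Source placements: the perinuclear source is an isotropic emitter *on* the
nuclear surface (standoff 0). This choice matters: the sub-keV half of the
Auger spectrum has ranges of tens of nanometres, so even a 0.1 µm standoff
removes most of its nuclear deposit and is not what "perinuclear
localization" means biologically. The standoff remains configurable
(`shell_eps_um`). The membrane source sits on the 13 µm cell surface, the
cytoplasmic source is uniform between nucleus and membrane.

The nuclear-to-average dose ratio divides the source-weighted nuclear
deposition fraction by the nuclear mass fraction (d_n/d_c)³ — at uniform
density the nucleus holds 33% of the cell's mass, so uniform deposition
gives a ratio of exactly 1.

## Nephron microdosimetry

The proximal tubule is an infinite annular cylinder: a 15 µm-radius lumen
(a typical proximal-tubule calibre; the source nephron model does not
reprint it) wrapped in a 10 µm epithelial wall. Tubule-cell nuclei are 5 µm
spheres centred mid-wall, one per epithelial cell of 14 µm lateral pitch —
the large proximal-tubule cell of the human-scale nephron model this
geometry descends from, giving an in-wall nuclear band packing of 0.067.
Tracks are discretized in 128 equal path-length steps (sub-0.1 µm boundary
blur) and partitioned among lumen, wall and beyond-wall; the nuclear share
of the wall deposit comes either from the mid-wall band times the packing
fraction (default; low variance) or from an explicit lattice of nuclear
spheres (validation mode; the two agree within a few percent).

Two free parameters deserve emphasis because the source nephron model does
not print them and they control the headline numbers:

* **Lateral cell pitch (14 µm).** The fraction of emitted energy reaching
  *any* nucleus scales directly with the nuclear packing of the mid-wall
  band. The 14 µm pitch reproduces the sub-1% nuclear energy fraction for
  apical-surface decays that full condensed-history transport yields in
  this geometry.
* **Kidney nuclear mass fraction (0.134).** The proximal-tubule nuclear
  dose rescales the whole-kidney electron dose as
  D_nuc = D_kidney × occupancy(0.43) × φ(nucleus←surface) / f_nuc.
  f_nuc is the nuclear share of kidney mass — the kidney holds nuclei of
  all nephron segments, glomeruli and interstitium, not only the sparse
  proximal-tubule wall nuclei, so it is kept as its own parameter with a
  cell-dense-cortex default of 0.134 rather than being derived from the
  wall packing. Every factor of the formula is returned in the provenance.

The model intentionally reports *average* tubule-cell nuclear dose under
uniform surface binding; real tubule uptake is heterogeneous, which would
spread (but not re-centre) the per-nucleus dose distribution. The
cytoplasmic share of surface decays in this geometry comes out somewhat
above the value a full condensed-history nephron simulation produces,
because straight-track CSDA transport back-loads deposition along the
track; the nuclear fraction — the quantity this module exists for — is far
less sensitive, and carries a wide tolerance in the tests for exactly this
reason. The glomerular dose rule is a passthrough of the photon channel
(electron contribution negligible at glomerular distances), and the
striated-duct worst case divides the salivary organ dose by a configurable
duct mass fraction (default 1/20).

## Synthetic data

Each tissue follows uptake-then-biexponential clearance,
m(t) = (1 − e^{−t/τ})·(A₁e^{−λ₁t} + A₂e^{−λ₂t}) in decay-corrected %ID/g,
with per-animal lognormal noise (default CV 0.2, the spread typical of
small-animal gamma-counting; means are noise-unbiased by construction).
The packaged presets emulate the study conditions: a PSMA+ tumor whose
concentration stays 2–3× the kidney's over weeks 1–3 and whose electron
coefficient lands near 2.6 Gy/MBq; a PSMA− tumor peaking near 1 %ID/g; a
kidney whose slow phase runs from 12.8 %ID/g at 2 weeks to 0.2 %ID/g at 12
weeks (sampled on the 2–12-week long-term schedule, so its unobserved early
phase exercises the head-extrapolation machinery); salivary gland
(≈12 mGy/MBq) and blood on the 1 h–3 week schedule. Closed-form TIAC truth
accompanies every generated table, and `recovery_experiment` measures
pipeline bias against it.

What the generator does *not* emulate: tumor-volume dynamics (the early
%ID/g "peak" from shrinking tumors is mimicked only via the uptake factor),
inter-animal kinetic variability (noise is measurement-like, not
mixed-effects), censoring other than the saturated-sample mechanism, and
multi-strain differences. Passing recovery tests therefore demonstrate
estimator correctness under the stated noise model, not robustness to every
feature of real biodistribution data.

## Numerical choices and problem sizes

* Seeds are mandatory for every stochastic routine; runs are exactly
  reproducible, and the RNG state of the caller is restored.
* Monte Carlo budgets used by the packaged analyses: 2×10⁵ histories per
  sphere (20 spheres), 2×10⁵ for the kidney ellipsoid, 10⁵ per cell
  compartment, 2×10⁵ per tubule source — each runs in seconds as a
  vectorized batch, and standard errors scale as histories^(−1/2).
* Photon transport interpolates photoelectric/incoherent coefficients on a
  240-point log-energy grid (1–200 keV) and samples Klein–Nishina by
  rejection from a uniform proposal in the scattered-energy ratio.
* The tail fit excludes non-positive values from the log fit with a
  warning; a constant tail gives R² = 1 by convention but fails
  integration (non-positive decay constant) with an explicit error.
* Head/tail continuity at the breakpoint is checked and warned about above
  10% mismatch — typically a sign the R² threshold admitted a breakpoint
  inside a still-multi-exponential region.

## Worked example

```{r, eval = FALSE}
report <- run_full_analysis(default_config(seed = 7))
print(report)
```

The report carries per-organ electron/photon coefficients and doses at the
configured activity, the sphere power-law fit and kidney absorbed fraction,
the cellular nuclear dose ratio and tumor nuclear dose, the tubule energy
partition and proximal-tubule nuclear dose, and the tumor:kidney nuclear
dose ratio, each with the inputs that produced it.

## Known limitations

* Electron transport is straight-track CSDA: no lateral scattering,
  energy-loss straggling or delta rays. Good for the nuclear deposition
  fractions tested here; not a general-purpose track-structure code.
* Photon transport ignores coherent scattering and electron-binding
  corrections to incoherent scattering; absorbed-fraction *levels* carry
  tens-of-percent systematic uncertainty, the mass exponent much less.
* Cross-organ photon dose, human phantoms, RBE/BED weighting, and
  multicellular/bystander effects are out of scope.
* The nephron free parameters (lumen radius, cell pitch, kidney nuclear
  fraction) are inherited/calibrated, not measured; conclusions that
  depend on them more tightly than a factor of ~2 need better anatomy.
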