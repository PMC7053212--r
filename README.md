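# augerdose

Macro-to-microscale internal dosimetry for Auger-electron
radiopharmaceutical therapy, built around the case of an ¹²⁵I-labelled,
PSMA-targeted small molecule in the mouse. The package is for
radiopharmaceutical scientists and medical physicists who need to go from
biodistribution tables (%ID/g time courses) all the way down to the dose
actually reaching cell nuclei — the scale that decides both tumor kill and
normal-tissue toxicity when the emitter's electrons travel less than 10 µm.

## What it computes

**Organ scale (MIRD schema).** Time-activity curves are fit to each
tissue's physical activity concentration with a hybrid
trapezoid/mono-exponential model (trapezoids over the early, irregular
points; an analytic exponential tail once the remaining points fit with
R² ≥ 0.9). Their integral is the time-integrated activity coefficient
Ã/A₀ (MBq·h/g per MBq injected), and the absorbed dose coefficient per
channel is

    D / A₀ = (Ã/A₀) · Δ · φ / m

with Δ the ICRP 107 energy per decay (19.2 keV electrons, 42.8 keV
photons for ¹²⁵I), φ the absorbed fraction (1 for electrons at organ
scale; Monte Carlo for photons) and m the target mass. Photon dose is
self-dose only.

**Photon absorbed fractions.** A seeded photon Monte Carlo
(photoelectric + Klein–Nishina scattering in water) gives absorbed
fractions for unit-density spheres from 0.001 to 100 g and for a 0.298 g
kidney ellipsoid, summarized by the power law AF(m) = a·m^b (AF in %, m in
g) fit in log-log space.

**Cell scale.** Straight-track continuous-slowing-down electron transport
(Cole range-energy relation) in a 26 µm cell with an 18 µm nucleus yields
the fraction of emitted electron energy reaching the nucleus from
perinuclear, membrane and cytoplasmic sources, by Monte Carlo or a
deterministic point kernel. The nuclear-to-average dose ratio is
Σᵢ fᵢφᵢ / w_nuc with fᵢ the source distribution and w_nuc = (d_n/d_c)³.

**Nephron scale.** The same electron transport in an annular proximal
tubule (15 µm lumen, 10 µm wall, 5 µm nuclei) partitions apical-surface
and cytoplasmic decay energy among nucleus, cytoplasm, lumen and
beyond-wall, and rescales the whole-kidney electron dose to the
proximal-tubule nuclei via
D_nuc = D_kidney · occupancy · φ(nucleus←surface) / f_nuc.

**Synthetic data.** Kinetic presets with uptake-then-biexponential
clearance, lognormal measurement noise and closed-form TIAC truth make the
whole pipeline testable end to end without any external data.

## Worked example

```r
library(augerdose)
report <- run_full_analysis(default_config(seed = 7))
print(report)
```

```
== Macro-to-microscale dosimetry report ==
<dose_report> injected activity 111 MBq
     organ electron_gy_per_mbq photon_gy_per_mbq electron_gy photon_gy total_gy
 pip_tumor             2.70954           0.61707     300.759    68.495  369.254
 flu_tumor             0.00581           0.00132       0.645     0.147    0.792
    kidney             0.72799           0.10723      80.807    11.903   92.710
  salivary             0.01208                NA       1.341        NA    1.341
     blood             0.00595                NA       0.661        NA    0.661
Power law: AF = 10.2 % * m^0.254 (R2 0.995); kidney photon AF 0.0661
Cell nuclear dose ratio 0.304 -> tumor nuclear dose 91.5 Gy
Tubule nuclei dose 1.87 Gy; tumor:tubule nuclear ratio 48.9
```

Reading the numbers: at 111 MBq the synthetic PSMA+ tumor receives ~300 Gy
from electrons while the PSMA− control gets under 1 Gy (uptake is
PSMA-mediated); the kidney receives ~81 Gy as an organ average — yet only
~1.9 Gy reaches proximal-tubule nuclei, because apically bound decays
spend their short-ranged electrons on lumen and cytoplasm. Tumor cells,
which internalize the ligand, concentrate ~91 Gy on their nuclei: a ~49×
nuclear dose differential from geometry alone. The power-law exponent
b ≈ 0.25 quantifies how the photon self-dose grows with tumor mass.

A YAML config with the same structure as `default_config()` can replace
the synthetic presets with a measured biodistribution CSV
(`tissue,time_h,pct_id_per_g,sd,n,flag`); a thin command-line wrapper is
installed at `inst/scripts/augerdose-report.R`.

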