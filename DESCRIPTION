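Package: augerdose
Title: Macro-to-Microscale Dosimetry for Auger-Electron Radiopharmaceutical Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Internal dosimetry pipeline for iodine-125 labelled,
    PSMA-targeted Auger-electron radiopharmaceuticals in the mouse.
    Builds hybrid trapezoid-exponential time-activity curves from
    biodistribution (%ID/g) tables, integrates them to time-integrated
    activity coefficients, and converts these to organ absorbed-dose
    coefficients with separate electron and photon channels following the
    MIRD schema.  Photon self-absorbed fractions are estimated with a
    seeded Monte Carlo photon transport in unit-density spheres and a
    scaled kidney ellipsoid, and summarised by a power-law fit in mass.
    Subcellular energy deposition is modelled with straight-track
    continuous-slowing-down electron transport in a concentric-sphere
    cell and in an annular nephron tubule, yielding tumor-nucleus versus
    kidney tubule-nucleus dose differentials.  A synthetic biodistribution
    generator with known kinetics supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
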