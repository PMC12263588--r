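Package: hemocoil
Title: Windkessel Calibration, 0D Hemodynamics, Virtual Coil Embolization
    and Wall Shear Indices for Aortic Arch Aneurysms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale hemodynamic modelling chain for stent-grafted and
    coil-embolized aortic arch aneurysms. Calibrates three-element Windkessel
    (RCR) outlet boundary conditions from patient-style pressure and inflow
    records, integrates a transient 0D lumped-parameter surrogate of the
    four-branch outlet network to periodic steady state, generates virtual
    coil-embolization centerlines (planar and helical morphologies) inside
    aneurysm sac surfaces under non-overlap and containment constraints,
    and computes time-averaged wall shear stress (TAWSS), oscillatory shear
    index (OSI) and relative residence time (RRT) maps with threshold area
    fractions. A synthetic-anatomy module supplies sac meshes, outlet sets,
    pulsatile waveforms and ground-truth wall-shear fields so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
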