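Package: glomsim
Title: Network Model of Glomerular Filtration, Shear and Hoop Stress
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Steady-state simulator of blood flow and filtration in the
    glomerular capillary network of the rat. Solves coupled node pressures,
    per-segment pressure/flow/protein profiles with distributed Starling
    filtration, erythrocyte phase separation at bifurcations, and
    hematocrit-dependent apparent viscosity, via a fixed-point iteration on
    filtration resistances and viscosities. Computes endothelial wall shear
    stress and Young-Laplace hoop stress per capillary segment, calibrates
    hydraulic conductivity and arteriolar resistances to micropuncture
    targets, and ships disease-condition presets (diabetes mellitus,
    5/6-nephrectomy, angiotensin II hypertension) plus a synthetic anatomy
    generator constrained to published morphometric statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    pracma,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
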