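Package: icrcell
Title: Electrostatic Evaluation of FT-ICR Measuring Cells
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Construction of classical ion cyclotron resonance (ICR)
    measuring-cell (Penning trap) geometries, computation of their trapping
    potentials by closed-form series or a finite-difference Laplace solver,
    least-squares extraction of the spherical-harmonic anharmonicity
    coefficients (A20, A40, A60) from the azimuthally averaged field,
    derivation of ion eigenfrequencies and ion-cloud dephasing ("comet
    formation") times, and analysis of the harmonic content of image-current
    detection signals including multielectrode frequency multiplication.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
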