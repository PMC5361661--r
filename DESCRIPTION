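Package: tamoxtrial
Title: Virtual Clinical Trials of Tamoxifen-Endoxifen Dosing Under CYP2D6 Pharmacogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates virtual clinical trials of tamoxifen adherence with a
    reduced linear kinetic model of tamoxifen and its active metabolites
    (N-desmethyltamoxifen, 4-hydroxytamoxifen, endoxifen), with CYP2D6
    genotype-scaled formation pathways. Provides virtual patient populations
    with log-normal inter-individual variability, dosing protocols with drug
    holidays and fixed-dose tamoxifen plus endoxifen combinations, daily
    trough extraction, a time-to-steady-state analysis against an extensive
    metabolizer benchmark, and calibration of the kinetic parameters to
    published trial observables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
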