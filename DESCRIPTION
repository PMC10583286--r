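Package: mqrelax
Title: Multiple-Quantum Methyl NMR Relaxation and Chemical Exchange Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of chemical exchange in 13CH3 methyl groups from
    multiple-quantum Hahn-echo and CPMG NMR relaxation measurements. Provides
    forward calculators for the dipolar, chemical shift anisotropy (CSA) and
    exchange contributions to zero-, double-, four-spin double- and
    quadruple-quantum (ZQ/DQ/DQ'/QQ) transverse relaxation rates, a two-state
    Bloch-McConnell exchange engine with closed-form and eigenvalue Hahn-echo
    exchange broadening and numerical CPMG dispersion simulation,
    field-dependence regression with (xi_H, xi_C) constraint-line and
    chi-square surface analysis, 13C quartet lineshape fitting for order
    parameter and CSA estimation, IPAP spin-state-selective 1H CSA
    determination, a global Levenberg-Marquardt joint fit of Hahn-echo and
    CPMG data, and a synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
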