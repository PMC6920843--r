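Package: nmrdfit
Title: Model-Free and Quadrupole-Enhanced Analysis of Solid-State NMR Relaxation Dispersion
Version: 0.1.0
Authors@R: person("nmrdfit", "maintainers", email = "nmrdfit@example.org", role = c("aut", "cre"))
Description: Forward models, simulation and fitting tools for 1H spin-lattice
    relaxation dispersion (NMRD) profiles of solid proteins measured by
    fast-field-cycling relaxometry. Implements the model-free three-Lorentzian
    decomposition of the 1H-1H dipolar relaxation rate, the closed-form
    1H-14N quadrupole relaxation enhancement (QRE) rate with its
    extreme-narrowing limit, and a stochastic Liouville equation (SLE)
    treatment of the 1H-14N contribution valid at arbitrary products of
    quadrupole frequency and correlation time. A staged fitting pipeline
    extracts quadrupole parameters from peak positions, correlation times
    from peak widths, and the remaining dynamical parameters by bounded
    nonlinear least squares. Includes a synthetic-profile generator and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
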