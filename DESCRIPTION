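Package: nanodrude
Title: Generalized Drude-Lorentz Carrier Transport in Nanostructures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Closed-form evaluation of a generalized Drude-Lorentz transport
    model for carriers in nanostructures: velocity autocorrelation function,
    time-dependent diffusion coefficient and mean-squared displacement in the
    overdamped, underdamped, critical and free-carrier (Drude) regimes, with
    carbon-nanotube carrier presets, an independent numerical-quadrature
    oracle, a toy ion-channel membrane state-enumeration module with
    probability-flux and information-geometry utilities (Kullback-Leibler
    divergence, Fisher information), and a command-line interface for curve,
    peak and membrane calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
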