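Package: linacsim
Title: First-Order Simulation of a Klystron-Driven Medical Linear
    Accelerator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytical first-order models of the photon-mode chain of a
    klystron-driven medical linear accelerator, from RF drive and pulse
    voltage settings through electron acceleration, bend-magnet energy
    selection, thick-target bremsstrahlung, flattening-filter and jaw
    shaping, to dose-rate and profile metrics in a water phantom. Intended
    for teaching beam tuning: service-mode controls map to the readouts a
    physicist or service engineer would watch (klystron output, gun and
    target current, beam energy, dose rate, flatness and symmetry), with
    presets for 6 and 15 MV beams, parameter sweeps and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
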