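Package: ifmpa
Title: Interferometric Micropipette Aspiration: Simulation, Demodulation
    and Viscoelastic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A software instrument for micropipette aspiration (MPA) with an
    all-optical interferometric readout. Provides a physics-forward simulator
    of a two-cavity, low-finesse Fabry-Perot fiber probe (fiber-to-sample
    cavity in medium plus a sealed MEMS pressure-sensor cavity), spectral
    phase demodulation of interferogram stacks into sub-nanometer displacement
    and pressure time series, Butterworth low-pass preprocessing, quasi-static
    elastic modulus extraction via the linearized Zhou/Plaza aspiration model,
    and dynamic mechanical analysis (storage/loss moduli, phase lag) with
    two-term power-law rheology fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
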