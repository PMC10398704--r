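Package: cntflow
Title: Continuum Lennard-Jones Model of Water Cluster Transport in Carbon Nanotubes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a cylindrical water cluster inside a carbon nanotube with
    the 6-12 Lennard-Jones potential under the continuum (surface-density)
    approximation. Provides the hypergeometric reduction of the
    cylinder-cylinder interaction integral, suction-energy optimisation of the
    cluster radius, a wall-friction model, and velocity-Verlet transport
    dynamics, together with wettability parameter sweeps, quartic
    critical-point extraction, and brute-force discrete/quadrature oracles for
    validation.
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
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
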