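Package: ecmosim
Title: Steady-State Gas-Exchange Simulation of Venous-Venous ECMO Support
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic simulator of cardiopulmonary physiology during
    venous-venous extracorporeal membrane oxygenation (VV-ECMO) support in
    severe respiratory failure. Computes the mechanical power delivered by
    the ventilator to the lungs, couples a single-pass membrane-oxygenator
    model with native-lung shunt exchange and tissue Fick exchange through a
    damped fixed-point solver to a whole-body steady state, and derives the
    oxygen partial-pressure stimulus of hypoxic pulmonary vasoconstriction.
    Includes blood gas content chemistry (Severinghaus oxyhemoglobin
    dissociation with Bohr correction, Douglas whole-blood CO2 content) with
    forward and inverse solvers, scenario configuration files, a packaged
    prototypical severe-ARDS case, and a parameter-sweep engine with CSV
    output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
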