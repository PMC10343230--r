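Package: oxyscav
Title: Kinetic Modelling of Enzymatic Oxygen Scavenging in Hypoxic Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward models and parameter estimation for enzymatic oxygen
    scavenging under hypoxic conditions. Implements pseudo-first-order
    dissolved-oxygen depletion in sealed (no-headspace) samples, the coupled
    glucose-oxidase/peroxidase/guaiacol consecutive-reaction chromogenic
    scheme, the headspace gas-to-liquid transfer versus scavenging balance
    with its steady-state analysis, and Stern-Volmer luminescence-lifetime
    oxygen-probe calibration. Includes Henry's-law solubility utilities, a
    synthetic-trace generator for Oxysense-style probe and stopped-flow
    absorbance experiments, nonlinear least-squares fitters for every scheme,
    and a small batch pipeline with CSV trace input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
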